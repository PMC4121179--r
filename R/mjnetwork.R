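# Reduced median-joining haplotype networks (Bandelt et al. 1999) over
# integer-coded character matrices: binary sites (Hamming) or STR repeat
# counts (weighted Manhattan / single-step distance). Characters here are
# linearly ordered states, for which the quasi-median of a triplet is the
# unique component-wise median vector.

#' Condense haplotypes into a character matrix
#'
#' Merges identical haplotypes, accumulating multiplicities and
#' per-population counts.
#'
#' @param haplotypes Integer matrix (samples x characters) or data frame;
#'   all rows must share the character set.
#' @param populations Optional per-sample population labels.
#' @param weights Per-character positive weights (default 1).
#' @return List of class `character_matrix`: `states` (taxa x characters),
#'   `multiplicity`, `pop_counts` (taxa x populations or `NULL`),
#'   `weights`.
#' @export
condense <- function(haplotypes, populations = NULL, weights = NULL) {
  m <- as.matrix(haplotypes)
  if (any(is.na(m))) stop("missing states not supported")
  storage.mode(m) <- "integer"
  if (is.null(weights)) weights <- rep(1, ncol(m))
  if (length(weights) != ncol(m) || any(weights <= 0))
    stop("weights must be positive, one per character")
  keys <- apply(m, 1L, paste, collapse = ",")
  ord <- order(keys)          # deterministic taxon ordering
  keys <- keys[ord]; m <- m[ord, , drop = FALSE]
  if (!is.null(populations)) populations <- populations[ord]
  first <- !duplicated(keys)
  states <- m[first, , drop = FALSE]
  idx <- match(keys, keys[first])
  mult <- as.vector(table(factor(idx, levels = seq_len(sum(first)))))
  pc <- NULL
  if (!is.null(populations))
    pc <- as.matrix(table(factor(idx, levels = seq_len(sum(first))),
                          populations))
  rownames(states) <- NULL
  structure(list(states = states, multiplicity = mult, pop_counts = pc,
                 weights = weights), class = "character_matrix")
}

mj_dist <- function(a, b, w) sum(w * abs(a - b))

mj_dist_matrix <- function(states, w) {
  n <- nrow(states)
  d <- matrix(0, n, n)
  if (n >= 2) for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- mj_dist(states[i, ], states[j, ], w)
  d
}

# sigma(u,v): smallest distance class at which u and v become connected in
# the greedy minimum-spanning process (using all pairs of distance <= class).
msn_sigma <- function(d) {
  n <- nrow(d)
  sigma <- matrix(Inf, n, n)
  comp <- seq_len(n)
  for (delta in sort(unique(d[upper.tri(d)]))) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      if (d[i, j] <= delta && comp[i] != comp[j])
        comp[comp == comp[j]] <- comp[i]
    newly <- is.infinite(sigma) & outer(comp, comp, "==")
    sigma[newly] <- delta
  }
  diag(sigma) <- 0
  sigma
}

# epsilon-relaxed minimum spanning network: links (u,v) with
# d(u,v) <= sigma(u,v) + epsilon.
msn_links <- function(d, epsilon) {
  sg <- msn_sigma(d)
  which(upper.tri(d) & d <= sg + epsilon + 1e-9, arr.ind = TRUE)
}

#' Build a median-joining haplotype network
#'
#' Iterates the Bandelt et al. (1999) scheme: connect the current node set
#' by the epsilon-relaxed minimum spanning network, propose quasi-medians
#' (component-wise median vectors) of triplets centred on shared
#' network neighbours, add those whose connection cost is within `epsilon`
#' of the round minimum, and repeat to a fixpoint; latent nodes that end up
#' with degree <= 1 are deleted. At `epsilon = 0` the result contains a
#' minimum spanning network of the observed haplotypes.
#'
#' @param cm A [condense()]d character matrix.
#' @param epsilon Nonnegative relaxation parameter (default 0).
#' @param reduced Light reduced-median preprocessing for binary data:
#'   characters with identical splits are merged into one character with
#'   summed weight before network construction (the full parallel-mutation
#'   cancellation of the reduced-median method is not implemented). STR
#'   data are never reduced.
#' @param max_medians Abort when more latent nodes than this are generated.
#' @return List of class `haplotype_network`: `nodes` (states matrix,
#'   observed taxa first), `median` (logical), `multiplicity`,
#'   `pop_counts`, `edges` (data frame `from`, `to`, `weight`, `characters`),
#'   `weights`.
#' @export
build_mj <- function(cm, epsilon = 0, reduced = FALSE, max_medians = 1e4) {
  stopifnot(inherits(cm, "character_matrix"), epsilon >= 0)
  w <- cm$weights
  if (reduced && all(cm$states %in% c(0L, 1L)) && ncol(cm$states) > 1) {
    key <- apply(cm$states, 2, paste, collapse = "")
    first <- !duplicated(key)
    w <- as.vector(tapply(w, factor(key, levels = key[first]), sum))
    cm$states <- cm$states[, first, drop = FALSE]
    cm$weights <- w
  }
  nodes <- cm$states
  n_obs <- nrow(nodes)
  keyset <- new.env(hash = TRUE, parent = emptyenv())
  nkey <- function(x) paste(x, collapse = ",")
  for (i in seq_len(n_obs)) assign(nkey(nodes[i, ]), TRUE, keyset)
  repeat {
    d <- mj_dist_matrix(nodes, w)
    links <- msn_links(d, epsilon)
    # candidate triplets: two links sharing a node
    adj <- vector("list", nrow(nodes))
    if (nrow(links)) for (r in seq_len(nrow(links))) {
      i <- links[r, 1]; j <- links[r, 2]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
    cand <- list(); costs <- numeric(0)
    for (u in seq_len(nrow(nodes))) {
      nb <- adj[[u]]
      if (length(nb) < 2) next
      prs <- utils::combn(sort(nb), 2)
      for (c2 in seq_len(ncol(prs))) {
        v <- prs[1, c2]; z <- prs[2, c2]
        med <- apply(nodes[c(u, v, z), , drop = FALSE], 2, stats::median)
        med <- as.integer(round(med))
        if (exists(nkey(med), keyset)) next
        cost <- mj_dist(nodes[u, ], med, w) + mj_dist(nodes[v, ], med, w) +
          mj_dist(nodes[z, ], med, w)
        cand <- c(cand, list(med)); costs <- c(costs, cost)
      }
    }
    if (!length(cand)) break
    keep <- costs <= min(costs) + epsilon + 1e-9
    added <- FALSE
    for (i in which(keep)) {
      k <- nkey(cand[[i]])
      if (!exists(k, keyset)) {
        assign(k, TRUE, keyset)
        nodes <- rbind(nodes, cand[[i]])
        added <- TRUE
      }
    }
    if (!added) break
    if (nrow(nodes) - n_obs > max_medians)
      stop("median generation exceeded ", max_medians,
           " latent nodes; input too heterogeneous for MJ")
  }
  # prune obsolete latent nodes: those of degree <= 1, and those whose
  # removal does not increase the spanning length of the node set (they
  # do not pay for themselves as Steiner points)
  repeat {
    d <- mj_dist_matrix(nodes, w)
    links <- msn_links(d, epsilon)
    deg <- tabulate(c(links[, 1], links[, 2]), nbins = nrow(nodes))
    drop <- which(deg <= 1 & seq_len(nrow(nodes)) > n_obs)
    if (!length(drop)) {
      cur_len <- mst_length(nodes, w)
      for (v in which(seq_len(nrow(nodes)) > n_obs)) {
        if (mst_length(nodes[-v, , drop = FALSE], w) <= cur_len + 1e-9) {
          drop <- v
          break
        }
      }
    }
    if (!length(drop)) break
    nodes <- nodes[-drop, , drop = FALSE]
  }
  d <- mj_dist_matrix(nodes, w)
  links <- msn_links(d, epsilon)
  edges <- data.frame(from = integer(0), to = integer(0), weight = numeric(0),
                      characters = character(0), stringsAsFactors = FALSE)
  if (nrow(links)) {
    chars <- colnames(cm$states) %||% paste0("c", seq_along(w))
    edges <- data.frame(
      from = links[, 1], to = links[, 2],
      weight = d[links],
      characters = vapply(seq_len(nrow(links)), function(r) {
        diffc <- which(nodes[links[r, 1], ] != nodes[links[r, 2], ])
        paste(chars[diffc], collapse = ",")
      }, ""),
      stringsAsFactors = FALSE)
  }
  mult <- c(cm$multiplicity, rep(0L, nrow(nodes) - n_obs))
  pc <- cm$pop_counts
  if (!is.null(pc))
    pc <- rbind(pc, matrix(0L, nrow(nodes) - n_obs, ncol(pc),
                           dimnames = list(NULL, colnames(pc))))
  structure(list(nodes = nodes,
                 median = seq_len(nrow(nodes)) > n_obs,
                 multiplicity = mult, pop_counts = pc, edges = edges,
                 weights = w, epsilon = epsilon),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf("<haplotype_network> %d nodes (%d median), %d edges, length %.1f\n",
              nrow(x$nodes), sum(x$median), nrow(x$edges), network_length(x)))
  invisible(x)
}

#' Length of a network
#'
#' The length of a minimum spanning tree over the network's node set
#' (observed plus inferred medians) under the weighted single-step
#' distance — the Steiner-tree value the medians realise. Never exceeds
#' the MST length of the observed haplotypes alone.
#'
#' @param net A `haplotype_network`.
#' @return Total length.
#' @export
network_length <- function(net) mst_length(net$nodes, net$weights)

mst_length <- function(states, w) {
  n <- nrow(states)
  if (n < 2) return(0)
  d <- mj_dist_matrix(states, w)
  intree <- c(TRUE, rep(FALSE, n - 1))
  mind <- d[1, ]
  tot <- 0
  for (step in seq_len(n - 1)) {
    i <- which(!intree)[which.min(mind[!intree])]
    tot <- tot + mind[i]
    intree[i] <- TRUE
    mind <- pmin(mind, d[i, ])
  }
  tot
}

#' Convert a haplotype network to igraph / export as GML
#'
#' Nodes carry `label`, `multiplicity`, `median` flags and per-population
#' counts; edges carry `weight` and the mutated characters.
#'
#' @param net A `haplotype_network`.
#' @return An igraph graph.
#' @export
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("from", "to")],
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(net$nodes))))
  igraph::V(g)$label <- apply(net$nodes, 1, paste, collapse = ",")
  igraph::V(g)$multiplicity <- net$multiplicity
  igraph::V(g)$median <- as.integer(net$median)
  if (!is.null(net$pop_counts))
    for (p in colnames(net$pop_counts))
      g <- igraph::set_vertex_attr(g, paste0("n_", p),
                                   value = net$pop_counts[, p])
  igraph::E(g)$weight <- net$edges$weight
  igraph::E(g)$characters <- net$edges$characters
  g
}

#' @rdname as_igraph
#' @param path Output GML file.
#' @return `write_network_gml`: `path`, invisibly.
#' @export
write_network_gml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "gml")
  invisible(path)
}
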