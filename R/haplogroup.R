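# Haplogroup trees and classification of Y-SNP profiles / HVS-I haplotypes.
#
# Trees are data: small JSON fixtures ship with the package (a Y panel
# topology and an mtDNA subtree), and users can supply their own phylotree
# builds in the same schema.

#' Construct a haplogroup tree
#'
#' @param nodes Named list: each element describes a node as a list with
#'   `parent` (name or `NA` for the root), `variants` (character vector of
#'   defining variants on the edge from the parent: Y-SNP marker names, or
#'   HVS-I motif tokens for mtDNA) and optionally `coding` (mtDNA
#'   coding-region SNP sites, as character).
#' @return An object of class `haplogroup_tree`.
#' @export
haplogroup_tree <- function(nodes) {
  stopifnot(is.list(nodes), !is.null(names(nodes)))
  if (anyDuplicated(names(nodes))) stop("duplicate haplogroup names")
  parents <- vapply(nodes, function(n) as.character(n$parent %||% NA_character_),
                    character(1))
  root <- names(nodes)[is.na(parents)]
  if (length(root) != 1L) stop("tree must have exactly one root")
  for (nm in names(nodes)) {
    p <- parents[[nm]]
    if (!is.na(p) && !p %in% names(nodes))
      stop("unknown parent '", p, "' of node '", nm, "'")
    if (!is.na(p) &&
        length(c(nodes[[nm]]$variants, nodes[[nm]]$coding)) == 0L)
      stop("edge into '", nm, "' carries no defining variants")
  }
  children <- lapply(names(nodes), function(nm) names(nodes)[parents == nm & !is.na(parents)])
  names(children) <- names(nodes)
  # cycle check: every node must reach the root
  for (nm in names(nodes)) {
    seen <- character(0); cur <- nm
    while (!is.na(parents[[cur]])) {
      if (cur %in% seen) stop("cycle detected at node '", cur, "'")
      seen <- c(seen, cur); cur <- parents[[cur]]
    }
  }
  structure(list(nodes = nodes, parent = parents, children = children,
                 root = root), class = "haplogroup_tree")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a haplogroup tree from a JSON file
#'
#' Schema: a nested object `{"name": ..., "variants": [...], "coding":
#' [...], "children": [...]}`; `variants` are Y-SNP marker names or HVS-I
#' motif tokens, `coding` optional mtDNA coding-region sites.
#'
#' @param path JSON file.
#' @return A [haplogroup_tree()].
#' @export
read_haplogroup_tree <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  nodes <- list()
  walk <- function(node, parent) {
    nm <- node$name
    nodes[[nm]] <<- list(parent = parent,
                         variants = as.character(unlist(node$variants)),
                         coding = as.character(unlist(node$coding)))
    for (ch in node$children %||% list()) walk(ch, nm)
  }
  walk(j, NA_character_)
  haplogroup_tree(nodes)
}

tree_path <- function(tree, name) {
  # names from root (exclusive) down to `name` (inclusive)
  out <- character(0); cur <- name
  while (!is.na(tree$parent[[cur]])) { out <- c(cur, out); cur <- tree$parent[[cur]] }
  out
}

tree_depth <- function(tree, name) length(tree_path(tree, name))

#' All markers occurring in a tree
#' @param tree A `haplogroup_tree`.
#' @return Character vector of edge-defining variant names.
#' @export
tree_markers <- function(tree)
  unique(unlist(lapply(tree$nodes, function(n) c(n$variants, n$coding))))

#' Is `anc` an ancestor of (or equal to) `node`?
#' @param tree A `haplogroup_tree`.
#' @param anc,node Node names; a trailing `"*"` is ignored.
#' @return Logical.
#' @export
is_ancestor <- function(tree, anc, node) {
  anc <- sub("\\*$", "", anc); node <- sub("\\*$", "", node)
  anc == tree$root || anc %in% tree_path(tree, node)
}

new_assignment <- function(sample_id, haplogroup, score, conflicts = character(0),
                           tied = FALSE, candidates = character(0)) {
  structure(list(sample_id = sample_id, haplogroup = haplogroup,
                 score = score, conflicts = conflicts, tied = tied,
                 candidates = candidates), class = "hg_assignment")
}

#' @export
print.hg_assignment <- function(x, ...) {
  cat(sprintf("<assignment> %s -> %s (score %.2f%s)\n", x$sample_id,
              x$haplogroup, x$score,
              if (x$tied) paste0("; tied: ", paste(x$candidates, collapse = ", "))
              else ""))
  invisible(x)
}

# State of the edge leading into `child`, summarised over its typed defining
# markers: "derived", "ancestral", "untyped" or "mixed".
edge_state <- function(tree, child, snp_states) {
  mk <- tree$nodes[[child]]$variants
  st <- snp_states[intersect(mk, names(snp_states))]
  st <- st[st != "untyped"]
  if (length(st) == 0L) return("untyped")
  if (all(st == "derived")) return("derived")
  if (all(st == "ancestral")) return("ancestral")
  "mixed"
}

#' Assign a Y haplogroup by hierarchical tree descent
#'
#' Walks the tree from the root, descending through edges whose typed
#' defining markers are derived. Fully untyped edges may be traversed only
#' when no typed sibling edge is derived (sibling exclusion) and further
#' derived evidence exists below; the reported node always has a derived
#' terminal edge. A `"*"` (paragroup) suffix is appended when at least one
#' child-defining marker was typed and all typed child edges are ancestral.
#'
#' @param profile A [y_profile()].
#' @param tree A [haplogroup_tree()] whose edge variants are marker names.
#' @return An `hg_assignment`. Haplogroup `"unresolved"` when no derived
#'   marker supports any clade. Derived states on mutually exclusive
#'   branches raise a conflict error listing the markers.
#' @export
assign_y <- function(profile, tree) {
  snp <- profile$snp_states
  # recursive search: returns list(node, score (derived markers on path),
  # depth) for the best terminal-derived node in the subtree, or NULL
  best_below <- function(node, score) {
    kids <- tree$children[[node]]
    states <- vapply(kids, edge_state, "", tree = tree, snp_states = snp)
    derived_kids <- kids[states == "derived"]
    if (length(derived_kids) > 1L) {
      mks <- unlist(lapply(derived_kids, function(k) {
        mk <- tree$nodes[[k]]$variants
        mk[snp[intersect(mk, names(snp))] == "derived"]
      }))
      stop("conflict: derived states on mutually exclusive branches (",
           paste(unique(mks), collapse = ", "), ")")
    }
    cand <- list()
    if (length(derived_kids) == 1L) {
      k <- derived_kids
      nder <- sum(snp[intersect(tree$nodes[[k]]$variants, names(snp))] == "derived")
      sub <- best_below(k, score + nder)
      cand <- c(cand, list(list(node = k, score = score + nder)), list(sub))
    } else {
      # sibling exclusion: untyped edges passable when no typed sibling
      # edge is derived; only nodes with derived evidence below count
      subs <- list()
      for (k in kids[states == "untyped"]) {
        sub <- best_below(k, score)
        if (!is.null(sub)) subs <- c(subs, list(sub))
      }
      if (length(subs) > 1L) {
        mks <- unlist(lapply(subs, function(s) {
          mk <- unlist(lapply(tree_path(tree, s$node),
                              function(p) tree$nodes[[p]]$variants))
          mk[snp[intersect(mk, names(snp))] == "derived"]
        }))
        stop("conflict: derived states on mutually exclusive branches (",
             paste(unique(mks), collapse = ", "), ")")
      }
      cand <- subs
    }
    cand <- Filter(Negate(is.null), cand)
    if (!length(cand)) return(NULL)
    depths <- vapply(cand, function(c) tree_depth(tree, c$node), 0L)
    cand[[which.max(depths)]]
  }
  res <- best_below(tree$root, 0L)
  if (is.null(res))
    return(new_assignment(profile$sample_id, "unresolved", 0L))
  node <- res$node
  kids <- tree$children[[node]]
  states <- vapply(kids, edge_state, "", tree = tree, snp_states = snp)
  star <- length(kids) > 0L && any(states == "ancestral") &&
    !any(states %in% c("derived", "mixed"))
  # conflicts: derived markers that belong to edges off the assigned path
  path <- c(tree_path(tree, node))
  off_path <- setdiff(names(tree$nodes), c(path, tree$root))
  conf <- character(0)
  for (nm in off_path) {
    if (nm %in% unlist(lapply(path, function(p) tree$children[[p]]))
        || nm %in% tree$children[[tree$root]]) next
    mk <- tree$nodes[[nm]]$variants
    der <- mk[snp[intersect(mk, names(snp))] == "derived"]
    if (length(der) && !any(vapply(path, function(p) nm %in% tree_path(tree, p), TRUE)))
      conf <- c(conf, der)
  }
  new_assignment(profile$sample_id,
                 paste0(node, if (star) "*" else ""),
                 res$score, conflicts = unique(conf))
}

#' Assign an mtDNA haplogroup from an HVS-I motif and coding SNPs
#'
#' Scores every node by `matched - lambda * missed` over its path-defining
#' variants, weighting coding-region matches by `coding_weight`. Untyped
#' coding sites never count for or against. Ties are reported, not broken.
#'
#' @param seq An [hvs1_sequence()].
#' @param coding Named character vector of coding-region SNP states
#'   (`"derived"`/`"ancestral"`/`"untyped"`), or `NULL` when none typed.
#' @param tree A [haplogroup_tree()] with HVS-I tokens in `variants` and
#'   coding sites in `coding`.
#' @param lambda Penalty per missed defining variant (default 0.5).
#' @param coding_weight Weight of a coding-region match (default 2).
#' @return An `hg_assignment`; `tied = TRUE` with all top candidates listed
#'   when several nodes share the maximal score. A `"*"` suffix marks
#'   paragroup status (no child's defining variants observed).
#' @export
assign_mt <- function(seq, coding = NULL, tree, lambda = 0.5,
                      coding_weight = 2) {
  if (length(tree$nodes) == 0L) stop("empty haplogroup tree")
  if (is.null(coding)) coding <- character(0)
  toks <- seq$variants$token
  node_score <- function(name) {
    path <- tree_path(tree, name)
    m <- 0; miss <- 0
    for (p in path) {
      hv <- tree$nodes[[p]]$variants
      # HVS-I variants outside the sequenced window cannot be observed
      hv_pos <- suppressWarnings(as.integer(sub("[^0-9].*$", "", hv)))
      in_win <- !is.na(hv_pos) & hv_pos >= seq$window[1] & hv_pos <= seq$window[2]
      m <- m + sum(hv[in_win] %in% toks)
      miss <- miss + sum(!(hv[in_win] %in% toks))
      cd <- tree$nodes[[p]]$coding
      st <- coding[intersect(cd, names(coding))]
      m <- m + coding_weight * sum(st == "derived")
      miss <- miss + sum(st == "ancestral")
    }
    m - lambda * miss
  }
  names_all <- names(tree$nodes)
  scores <- vapply(names_all, node_score, 0)
  top <- max(scores)
  winners <- names_all[scores >= top - 1e-9]
  if (length(winners) > 1L) {
    # a tie among nodes on one root-to-tip path resolves to the deepest;
    # ties across branches are reported, not broken
    depths <- vapply(winners, tree_depth, 0L, tree = tree)
    deepest <- winners[which.max(depths)]
    chain <- all(winners %in% c(tree$root, tree_path(tree, deepest)))
    if (!chain || sum(depths == max(depths)) > 1L)
      return(new_assignment(seq$sample_id, winners[1], top, tied = TRUE,
                            candidates = winners))
    winners <- deepest
  }
  node <- winners
  kids <- tree$children[[node]]
  child_observed <- any(vapply(kids, function(k) {
    hv <- tree$nodes[[k]]$variants
    cd <- tree$nodes[[k]]$coding
    any(hv %in% toks) ||
      any(coding[intersect(cd, names(coding))] == "derived")
  }, TRUE))
  star <- length(kids) > 0L && !child_observed && node != tree$root
  new_assignment(seq$sample_id, paste0(node, if (star) "*" else ""),
                 scores[[node]])
}

#' Classify a whole dataset
#'
#' @param x List of `y_profile` (for `classify_y`) or of `hvs1_seq`
#'   (for `classify_mt`).
#' @param tree A [haplogroup_tree()].
#' @param coding Optional named list of per-sample coding-SNP state vectors,
#'   keyed by `sample_id`.
#' @param ... Passed to [assign_y()] / [assign_mt()].
#' @return Data frame with `sample_id`, `population`, `haplogroup`, `score`,
#'   `tied`.
#' @export
classify_y <- function(x, tree, ...) {
  rows <- lapply(x, function(p) {
    a <- assign_y(p, tree, ...)
    data.frame(sample_id = p$sample_id, population = p$population,
               haplogroup = a$haplogroup, score = a$score, tied = a$tied,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @rdname classify_y
#' @export
classify_mt <- function(x, tree, coding = NULL, ...) {
  rows <- lapply(x, function(s) {
    cd <- if (!is.null(coding)) coding[[s$sample_id]] else NULL
    a <- assign_mt(s, cd, tree, ...)
    data.frame(sample_id = s$sample_id, population = s$population,
               haplogroup = a$haplogroup, score = a$score, tied = a$tied,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Bundled haplogroup tree fixtures
#'
#' `y_panel_tree()` covers the SNP panel topology used for classification of
#' East Asian Y lineages; `mt_subtree()` is a compact mtDNA subtree over the
#' haplogroups handled by the synthetic-data generator. Both are small,
#' versioned fixtures, not full phylotree builds.
#'
#' @return A [haplogroup_tree()].
#' @export
y_panel_tree <- function()
  read_haplogroup_tree(uniparent_extdata("y_tree.json"))

#' @rdname y_panel_tree
#' @export
mt_subtree <- function()
  read_haplogroup_tree(uniparent_extdata("mt_tree.json"))
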