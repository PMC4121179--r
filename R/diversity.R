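# Molecular diversity indices: gene (haplotype) diversity, mean pairwise
# differences, nucleotide diversity, polymorphic-site and haplotype counts.

#' Gene (haplotype) diversity with sampling variance
#'
#' \eqn{H = \frac{n}{n-1}(1 - \sum p_i^2)} with the Nei (1987) sampling
#' variance
#' \eqn{V(H) = \frac{2}{n(n-1)}\left[2(n-2)\left(\sum p_i^3 -
#' (\sum p_i^2)^2\right) + \sum p_i^2 - (\sum p_i^2)^2\right]}.
#'
#' @param counts Haplotype multiplicities (any order).
#' @return List with `value`, `variance`, `sd`, `n`.
#' @export
gene_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("gene diversity requires n >= 2")
  p <- counts / n
  s2 <- sum(p^2); s3 <- sum(p^3)
  H <- n / (n - 1) * (1 - s2)
  V <- 2 / (n * (n - 1)) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  list(value = H, variance = V, sd = sqrt(max(V, 0)), n = n)
}

# Pairwise distance matrix over variant token sets.
pairwise_distance_matrix <- function(seqs, exclude_indels = TRUE,
                                     window = NULL) {
  toks <- lapply(seqs, seq_tokens, exclude_indels = exclude_indels,
                 window = window)
  n <- length(toks)
  d <- matrix(0, n, n)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- token_distance(toks[[i]], toks[[j]])
    }
  }
  d
}

#' Mean number of pairwise differences (MNPD)
#'
#' Average symmetric-difference size of variant sets over all sample pairs
#' (indels excluded by default). The variance is the total (stochastic +
#' sampling) variance of Tajima (1993) as reported by Arlequin:
#' \eqn{V = \frac{3n(n+1)\hat\pi + 2(n^2+n+3)\hat\pi^2}{11(n^2-7n+6)}}.
#'
#' @param seqs List of `hvs1_seq`.
#' @param exclude_indels Drop insertion/deletion variants before comparing.
#' @return List with `value`, `variance`, `sd`, `n`.
#' @export
mean_pairwise_diff <- function(seqs, exclude_indels = TRUE) {
  n <- length(seqs)
  if (n < 2) stop("MNPD requires n >= 2")
  d <- pairwise_distance_matrix(seqs, exclude_indels)
  pi_hat <- sum(d[upper.tri(d)]) / (n * (n - 1) / 2)
  V <- (3 * n * (n + 1) * pi_hat + 2 * (n^2 + n + 3) * pi_hat^2) /
    (11 * (n^2 - 7 * n + 6))
  list(value = pi_hat, variance = V, sd = sqrt(max(V, 0)), n = n)
}

#' Count polymorphic sites and distinct haplotypes
#'
#' A site is polymorphic when at least two states (the reference counting
#' as one) segregate among the samples at that position. Haplotypes are
#' distinct variant sets.
#'
#' @param seqs List of `hvs1_seq`.
#' @param exclude_indels Drop indel variants first (default, matching the
#'   distance convention).
#' @return List with `S` (polymorphic sites) and `h` (haplotypes).
#' @export
count_sites_and_haplotypes <- function(seqs, exclude_indels = TRUE) {
  toks <- lapply(seqs, seq_tokens, exclude_indels = exclude_indels)
  n <- length(seqs)
  tab <- table(unlist(lapply(toks, unique)))
  # a token carried by every sample is fixed relative to the sample unless
  # another state segregates at the same position
  pos_of <- function(tk) as.integer(sub("[^0-9].*$", "", tk))
  seg <- names(tab)[tab < n]
  fixed <- names(tab)[tab == n]
  seg_pos <- unique(pos_of(seg))
  # fixed tokens still make the site polymorphic if a second derived state
  # exists there (already covered when that state is segregating)
  fixed_pos <- unique(pos_of(fixed))
  multi <- fixed_pos[vapply(fixed_pos, function(p)
    sum(pos_of(names(tab)) == p) > 1L, TRUE)]
  S <- length(union(seg_pos, multi))
  keys <- vapply(toks, function(t) paste(sort(t), collapse = "|"), "")
  list(S = S, h = length(unique(keys)))
}

#' Full molecular diversity summary for one sample set
#'
#' @param seqs List of `hvs1_seq`.
#' @param L Alignment length used for per-site nucleotide diversity
#'   (default: the window length of the first sequence).
#' @param exclude_indels Drop indels from distances (default `TRUE`).
#' @return List of class `diversity_summary` with `n`, `h`, `S`,
#'   `gene_diversity`, `mnpd`, `nucleotide_diversity` (each value/sd pairs)
#'   and `L`.
#' @export
diversity_summary <- function(seqs, L = NULL, exclude_indels = TRUE) {
  n <- length(seqs)
  if (is.null(L)) {
    w <- seqs[[1]]$window
    L <- w[2] - w[1] + 1L
  }
  keys <- vapply(seqs, function(s)
    paste(sort(seq_tokens(s, exclude_indels)), collapse = "|"), "")
  gd <- gene_diversity(as.vector(table(keys)))
  mp <- mean_pairwise_diff(seqs, exclude_indels)
  sh <- count_sites_and_haplotypes(seqs, exclude_indels)
  structure(list(n = n, h = sh$h, S = sh$S,
                 gene_diversity = gd,
                 mnpd = mp,
                 nucleotide_diversity = list(value = mp$value / L,
                                             variance = mp$variance / L^2,
                                             sd = mp$sd / L),
                 L = L),
            class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat(sprintf("n=%d  h=%d  S=%d  H=%.4f (sd %.4f)  MNPD=%.3f (sd %.3f)  ND=%.4f\n",
              x$n, x$h, x$S, x$gene_diversity$value, x$gene_diversity$sd,
              x$mnpd$value, x$mnpd$sd, x$nucleotide_diversity$value))
  invisible(x)
}

#' Per-population and pooled diversity table
#'
#' @param seqs List of `hvs1_seq`.
#' @param L Alignment length (see [diversity_summary()]).
#' @param pooled_label Label for the pooled row.
#' @return Data frame, one row per population plus a pooled row.
#' @export
diversity_table <- function(seqs, L = NULL, pooled_label = "pooled") {
  pops <- vapply(seqs, `[[`, "", "population")
  groups <- split(seqs, pops)
  groups[[pooled_label]] <- seqs
  rows <- lapply(names(groups), function(g) {
    s <- diversity_summary(groups[[g]], L)
    data.frame(population = g, N = s$n, h = s$h, S = s$S,
               haplotype_diversity = s$gene_diversity$value,
               haplotype_diversity_sd = s$gene_diversity$sd,
               MNPD = s$mnpd$value, MNPD_sd = s$mnpd$sd,
               nucleotide_diversity = s$nucleotide_diversity$value,
               nucleotide_diversity_sd = s$nucleotide_diversity$sd,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
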