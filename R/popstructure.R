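# Haplogroup frequency tables, frequency PCA, pairwise Y-STR population
# distances (R_ST / haplotype F_ST) and neighbour-joining trees.

#' Haplogroup frequency table
#'
#' @param assignments Data frame with `population` and `haplogroup`
#'   columns (e.g. from [classify_y()]).
#' @param populations Optional population ordering; unknown labels in the
#'   data raise an error.
#' @param haplogroups Optional haplogroup column ordering.
#' @return List of class `freq_table`: `populations`, `haplogroups`,
#'   `counts` (matrix), `frequencies` (row-normalised; all-zero rows stay
#'   zero).
#' @export
frequency_table <- function(assignments, populations = NULL,
                            haplogroups = NULL) {
  stopifnot(all(c("population", "haplogroup") %in% names(assignments)))
  if (is.null(populations)) populations <- sort(unique(assignments$population))
  unknown <- setdiff(assignments$population, populations)
  if (length(unknown)) stop("unknown population label: ", unknown[1])
  if (is.null(haplogroups)) haplogroups <- sort(unique(assignments$haplogroup))
  counts <- as.matrix(table(factor(assignments$population, populations),
                            factor(assignments$haplogroup, haplogroups)))
  tot <- rowSums(counts)
  freqs <- counts / ifelse(tot > 0, tot, 1)
  structure(list(populations = populations, haplogroups = haplogroups,
                 counts = counts, frequencies = freqs),
            class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat("<freq_table> ", length(x$populations), " populations x ",
      length(x$haplogroups), " haplogroups\n", sep = "")
  print(round(100 * x$frequencies, 2))
  invisible(x)
}

#' Percentage of samples in a set of haplogroups
#'
#' @param ft A `freq_table`.
#' @param haplogroups Haplogroup labels (exact match).
#' @param population One population, or `NULL` for the pooled total.
#' @return Percentage (0-100).
#' @export
haplogroup_percent <- function(ft, haplogroups, population = NULL) {
  cols <- intersect(haplogroups, colnames(ft$counts))
  if (is.null(population)) {
    100 * sum(ft$counts[, cols, drop = FALSE]) / sum(ft$counts)
  } else {
    100 * sum(ft$counts[population, cols, drop = FALSE]) /
      sum(ft$counts[population, ])
  }
}

#' PCA of haplogroup frequencies
#'
#' Eigen-decomposition of the column-centred (covariance mode) or
#' standardised (correlation mode) population-by-haplogroup frequency
#' matrix, populations as observations.
#'
#' @param ft A [frequency_table()] (or a plain frequency matrix).
#' @param mode `"covariance"` (classical haplogroup-frequency PCA,
#'   default) or `"correlation"`.
#' @return List of class `pca_result`: `scores` (population x PC),
#'   `loadings` (haplogroup x PC, orthonormal), `explained_fraction`,
#'   `degenerate` flag (zero total variance).
#' @export
hg_pca <- function(ft, mode = c("covariance", "correlation")) {
  mode <- match.arg(mode)
  x <- if (inherits(ft, "freq_table")) ft$frequencies else as.matrix(ft)
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("PCA requires at least 2 populations and 2 haplogroups")
  if (mode == "correlation") {
    keep <- apply(x, 2, stats::sd) > 0
    if (!all(keep)) warning("dropping zero-variance columns in correlation mode")
    x <- x[, keep, drop = FALSE]
  }
  if (all(apply(x, 2, stats::sd) == 0)) {
    return(structure(list(scores = NULL, loadings = NULL,
                          explained_fraction = NULL, degenerate = TRUE),
                     class = "pca_result"))
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = (mode == "correlation"))
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x, loadings = pc$rotation,
                 explained_fraction = expl, degenerate = FALSE),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  if (x$degenerate) { cat("<pca_result> degenerate input\n"); return(invisible(x)) }
  cat("<pca_result> explained: ",
      paste(sprintf("%.1f%%", 100 * x$explained_fraction[1:min(3, length(x$explained_fraction))]),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Pairwise population distances from Y-STR haplotypes
#'
#' `mode = "rst"` (default) is the microsatellite R_ST in the Arlequin
#' convention: a distance-based AMOVA on sums of squared repeat-size
#' differences for each population pair, with
#' \eqn{R_{ST} = \sigma^2_a / (\sigma^2_a + \sigma^2_w)} from the among/
#' within variance components. `mode = "fst"` replaces the squared size
#' distance by haplotype non-identity. Negative estimates are clamped to
#' zero (flagged in the `"clamped"` attribute).
#'
#' @param haplotypes Integer matrix samples x loci.
#' @param populations Per-sample population labels (>= 2 populations).
#' @param mode `"rst"` or `"fst"`.
#' @param loci Optional locus subset (e.g. the 6 classical dating loci).
#' @return Symmetric `dist_matrix` (list with `populations`, `d`).
#' @export
pairwise_str_distance <- function(haplotypes, populations,
                                  mode = c("rst", "fst"), loci = NULL) {
  mode <- match.arg(mode)
  if (!is.null(loci)) haplotypes <- haplotypes[, loci, drop = FALSE]
  pops <- sort(unique(populations))
  if (length(pops) < 2) stop("need at least two populations")
  sqd <- function(i, j) {
    if (mode == "rst") sum((haplotypes[i, ] - haplotypes[j, ])^2)
    else as.numeric(any(haplotypes[i, ] != haplotypes[j, ]))
  }
  sum_sq_pairs <- function(idx1, idx2 = NULL) {
    tot <- 0
    if (is.null(idx2)) {
      if (length(idx1) >= 2)
        for (a in seq_len(length(idx1) - 1)) for (b in (a + 1):length(idx1))
          tot <- tot + sqd(idx1[a], idx1[b])
    } else {
      for (a in idx1) for (b in idx2) tot <- tot + sqd(a, b)
    }
    tot
  }
  np <- length(pops)
  d <- matrix(0, np, np, dimnames = list(pops, pops))
  clamped <- FALSE
  for (i in seq_len(np - 1)) for (j in (i + 1):np) {
    ii <- which(populations == pops[i]); jj <- which(populations == pops[j])
    ni <- length(ii); nj <- length(jj); N <- ni + nj
    # distance-based AMOVA (squared distances already carry the factor 2
    # relative to variance components, which cancels in the ratio)
    ss_w <- sum_sq_pairs(ii) / ni + sum_sq_pairs(jj) / nj
    ss_tot <- (sum_sq_pairs(ii) + sum_sq_pairs(jj) +
                 sum_sq_pairs(ii, jj)) / N
    ss_a <- ss_tot - ss_w
    ms_w <- ss_w / (N - 2)
    n0 <- N - (ni^2 + nj^2) / N
    sigma_a <- (ss_a / 1 - ms_w) / n0
    val <- if (sigma_a + ms_w > 0) sigma_a / (sigma_a + ms_w) else 0
    if (val < 0) { val <- 0; clamped <- TRUE }
    d[i, j] <- d[j, i] <- val
  }
  structure(list(populations = pops, d = d),
            class = "dist_matrix", clamped = clamped)
}

#' Neighbour-joining tree from a population distance matrix
#'
#' Saitou-Nei neighbour joining (via ape); additive distances are
#' recovered exactly.
#'
#' @param dm A `dist_matrix` from [pairwise_str_distance()], or a plain
#'   symmetric matrix with dimnames.
#' @return An `ape::phylo` tree.
#' @export
neighbor_joining <- function(dm) {
  m <- if (inherits(dm, "dist_matrix")) dm$d else as.matrix(dm)
  if (any(!is.finite(m))) stop("non-finite distance entries")
  if (nrow(m) < 3) stop("neighbour joining requires at least 3 populations")
  ape::nj(stats::as.dist(m))
}

#' Write a tree in newick format
#' @param tree An `ape::phylo`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
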