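# Shared fixtures, built in code.

# Ten HVS-I haplotypes with 12 segregating transitions; the ancestral
# (outgroup) haplotype is rCRS-identical. Spectrum: n=10, S=eta=12,
# pi=3.9111, eta_s=eta_e=6, k=10. Statistic values frozen from an
# independent reference implementation (and, for F*, from the
# Simonsen-corrected coefficients).
toy_motifs <- c(
  "16110-16140", "16112-16146-16148", "", "16110-16112", "16132",
  "16110-16121-16134", "16108-16112-16146",
  "16108-16112-16121-16123-16132", "16124-16132", "16110-16146-16150")

toy_seqs <- function() {
  hvs1_dataset(data.frame(sample_id = paste0("s", seq_along(toy_motifs)),
                          population = "P", motif = toy_motifs,
                          stringsAsFactors = FALSE))
}

toy_oracle <- list(n = 10L, S = 12L, eta = 12L, eta_s = 6L, eta_e = 6L,
                   pi = 3.9111111, k = 10L,
                   tajima_d = -0.3521497,
                   fu_li_d = -0.7013919, fu_li_f = -0.7317203,
                   fu_li_d_star = -0.4059270, fu_li_f_star = -0.4418682,
                   fu_fs = -7.0007253)

# full-panel Y profile with the given markers derived, everything else at
# `default` ("untyped" or "ancestral")
y_profile_with <- function(derived, default = "untyped",
                           ancestral = character(0), id = "s") {
  tree <- y_panel_tree()
  st <- stats::setNames(rep(default, length(tree_markers(tree))),
                        tree_markers(tree))
  st[derived] <- "derived"
  st[ancestral] <- "ancestral"
  y_profile(id, "pop", st)
}

# brute-force minimum Steiner length over binary vectors: try all subsets
# of candidate latent points of size <= max_extra
steiner_min_length <- function(obs, max_extra = 2) {
  nc <- ncol(obs)
  cand <- as.matrix(expand.grid(rep(list(0:1), nc)))
  keys <- apply(obs, 1, paste, collapse = "")
  cand <- cand[!apply(cand, 1, paste, collapse = "") %in% keys, , drop = FALSE]
  w <- rep(1, nc)
  best <- uniparent:::mst_length(obs, w)
  for (k in seq_len(max_extra)) {
    combos <- utils::combn(nrow(cand), k)
    for (j in seq_len(ncol(combos))) {
      len <- uniparent:::mst_length(rbind(obs, cand[combos[, j], , drop = FALSE]), w)
      if (len < best) best <- len
    }
  }
  best
}

expect_close <- function(object, expected, tol) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("%.6g (expected %.6g +/- %g)", object,
                              expected, tol))
}
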