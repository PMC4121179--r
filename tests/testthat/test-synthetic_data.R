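test_that("allocate_counts rounds a mix deterministically to n", {
  mix <- c(a = 0.4444, b = 0.3333, c = 0.2223)
  cnt <- allocate_counts(mix, 18)
  expect_equal(sum(cnt), 18L)
  expect_equal(unname(cnt["a"]), 8L)
  expect_error(allocate_counts(c(a = 0.5), 10), "1")
})

test_that("the bundled study design reproduces the published sample sizes", {
  ys <- study_design("y"); ms <- study_design("mt")
  expect_equal(vapply(ys, `[[`, 0L, "n_samples"),
               c(DB = 18L, DF = 16L, XL = 46L, YJ = 47L))
  expect_equal(sum(vapply(ys, `[[`, 0L, "n_samples")), 127L)
  expect_equal(vapply(ms, `[[`, 0L, "n_samples"),
               c(DB = 46L, DF = 40L, XL = 119L, YJ = 192L))
  expect_equal(sum(vapply(ms, `[[`, 0L, "n_samples")), 397L)
})

test_that("generators are seed-deterministic and round-trip losslessly", {
  a <- generate_mt_dataset(study_design("mt"), seed = 14)
  b <- generate_mt_dataset(study_design("mt"), seed = 14)
  expect_identical(hvs1_table(a$seqs), hvs1_table(b$seqs))
  expect_identical(a$truth, b$truth)
  c2 <- generate_mt_dataset(study_design("mt"), seed = 15)
  expect_false(identical(hvs1_table(a$seqs), hvs1_table(c2$seqs)))
  # file round trip
  f <- tempfile(fileext = ".tsv")
  write_motif_table(a$seqs, f)
  expect_identical(hvs1_table(read_motif_table(f)), hvs1_table(a$seqs))
  ya <- generate_y_dataset(study_design("y"), seed = 14)
  yb <- generate_y_dataset(study_design("y"), seed = 14)
  expect_identical(lapply(ya$profiles, `[[`, "str_alleles"),
                   lapply(yb$profiles, `[[`, "str_alleles"))
})

test_that("zero mutation rate leaves founder motifs untouched (rho = 0)", {
  sp <- list(population_spec("P", counts = c(G2a = 6, D4 = 4)))
  d <- generate_mt_dataset(sp, mu_window = 0, seed = 2)
  founders <- read_founders()
  g2a <- d$seqs[d$truth$haplogroup == "G2a"]
  expect_true(all(vapply(g2a, function(s)
    format_motif(s$variants) == founders[["G2a"]], TRUE)))
  expect_equal(rho(g2a, founders[["G2a"]]), 0)
})

test_that("disjoint population mixes separate completely on PC1", {
  sp <- list(population_spec("north", counts = c(A4 = 10, D4 = 10)),
             population_spec("south", counts = c(B4 = 10, F1 = 10)))
  d <- generate_mt_dataset(sp, mu_window = 0, seed = 3)
  cls <- classify_mt(d$seqs, mt_subtree(), coding = d$coding)
  ft <- frequency_table(cls)
  pc <- hg_pca(ft)
  expect_equal(pc$explained_fraction[1], 1, tolerance = 1e-9)
})

test_that("star-demography clade ages are recovered end-to-end by rho dating", {
  # explosive growth from a tiny ancestral size makes the genealogy a
  # near-star of age t_onset: every lineage's path back to the founder is
  # ~ t_onset + 2*N_anc*(1 - 1/n) generations. The generated clade, dated
  # with the same clock the generator uses, must recover that age within
  # Monte Carlo error (finite-sites back mutation gives a small downward
  # bias, allowed for at 2%).
  set.seed(8)
  clock <- HVS1_CLOCK_YEARS_PER_MUTATION
  n <- 30; onset <- 420; N_anc <- 2
  expected <- onset + 2 * N_anc * (1 - 1 / n)
  sp <- list(population_spec("P", counts = c(D4 = n),
                             demography = demographic_model(
                               N_anc, alpha = 1, t_onset = onset)))
  founders <- read_founders()
  reps <- 200
  est <- replicate(reps, {
    d <- generate_mt_dataset(sp, seed = sample.int(1e6, 1))
    rho(d$seqs, founders[["D4"]], window = c(16024, 16488)) * clock / 25
  })
  se <- stats::sd(est) / sqrt(reps)
  expect_close(mean(est), expected, 3 * se + 0.02 * expected)
})
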