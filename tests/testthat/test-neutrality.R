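test_that("Tajima's D matches hand evaluation and the reference values", {
  # n=4, three singleton mutations: pi = 1.5, S = 3 -> -0.754 by direct
  # evaluation of the 1989 constants
  expect_close(tajimas_d(4, 3, 1.5), -0.754, 0.001)
  expect_true(is.na(tajimas_d(10, 0, 0)))
  expect_error(tajimas_d(3, 5, 1), "n >= 4")
  sp <- spectrum_summary(toy_seqs(), outgroup = "")
  expect_equal(sp[c("n", "S", "eta", "eta_s", "eta_e", "k")],
               toy_oracle[c("n", "S", "eta", "eta_s", "eta_e", "k")])
  expect_close(tajimas_d(sp$n, sp$S, sp$pi), toy_oracle$tajima_d, 1e-6)
})

test_that("Fu & Li's D, F, D*, F* match the frozen reference values", {
  sp <- spectrum_summary(toy_seqs(), outgroup = "")
  fl <- fu_li_tests(sp$n, sp$eta, sp$eta_e, sp$pi, outgroup = TRUE)
  expect_close(fl$D, toy_oracle$fu_li_d, 1e-6)
  expect_close(fl$F, toy_oracle$fu_li_f, 1e-6)
  fls <- fu_li_tests(sp$n, sp$eta, sp$eta_s, sp$pi, outgroup = FALSE)
  expect_close(fls$D, toy_oracle$fu_li_d_star, 1e-6)
  expect_close(fls$F, toy_oracle$fu_li_f_star, 1e-6)
  # monomorphic -> undefined sentinels
  expect_true(all(is.na(unlist(fu_li_tests(10, 0, 0, 0, TRUE)))))
  # n=5, all mutations singletons, coincident outgroup root: D < 0 forced
  # by the singleton excess
  sing <- hvs1_dataset(data.frame(
    sample_id = paste0("q", 1:5), population = "P",
    motif = c("16100", "16150", "16200", "16250", "16300")))
  spx <- spectrum_summary(sing, outgroup = "")
  flx <- fu_li_tests(spx$n, spx$eta, spx$eta_e, spx$pi, outgroup = TRUE)
  expect_lt(flx$D, 0)
})

test_that("Fu's Fs agrees with exact Ewens enumeration", {
  # exact: n=3, k=2, theta=1: |s(3,.)| = {2,3,1}, rising factorial 6
  expect_equal(fus_fs(3, 2, 1), log(2), tolerance = 1e-12)
  # K >= 1 always: +Inf sentinel with warning
  expect_warning(v <- fus_fs(3, 1, 1), "underflow")
  expect_identical(v, Inf)
  expect_true(is.na(fus_fs(10, 3, 0)))
  # log-space recurrence vs exact integer Stirling numbers for n <= 12
  exact_stirling <- function(n) {
    s <- 1
    if (n > 1) for (m in 1:(n - 1)) s <- c(0, s) + m * c(s, 0)
    s  # |s(n, k)| for k = 1..n
  }
  for (n in c(2, 5, 8, 12)) {
    expect_equal(uniparent:::log_stirling_row_raw(n), log(exact_stirling(n)),
                 tolerance = 1e-10)
    for (k in c(1L, ceiling(n / 2), n)) {
      theta <- 2.5
      st <- exact_stirling(n)
      pk <- st * theta^(seq_len(n)) / prod(theta + 0:(n - 1))
      Sp <- sum(pk[k:n])
      expected <- if (k == 1) Inf else log(Sp / (1 - Sp))
      expect_equal(suppressWarnings(fus_fs(n, k, theta)), expected,
                   tolerance = 1e-9)
    }
  }
  # frozen reference value on the toy data
  sp <- spectrum_summary(toy_seqs())
  expect_close(fus_fs(sp$n, sp$k, sp$pi), toy_oracle$fu_fs, 1e-6)
})

test_that("statistics are invariant to sample ordering", {
  s <- toy_seqs()
  set.seed(9)
  s2 <- s[sample(length(s))]
  for (f in list(function(x) spectrum_summary(x)$pi,
                 function(x) tajimas_d(10, 12, spectrum_summary(x)$pi),
                 function(x) diversity_summary(x)$gene_diversity$value))
    expect_equal(f(s), f(s2))
})

test_that("simulation p-values behave at the edges and at the median", {
  set.seed(31)
  # constant statistic: p = 1 under <=-tail with ties counted
  expect_equal(simulate_pvalue(function(n, S, pi, xi1, k) 0, 0, 20,
                               S = 10, reps = 500), 1)
  # an extreme negative Tajima's D is in the far lower tail
  expect_lt(simulate_pvalue("tajima_d", -3, 50, S = 30, reps = 2000), 0.05)
  # self-consistency: the median of the null has p ~= 0.5
  null <- coalescent_null_stats(25, 3000, S = 15)
  d <- uniparent:::null_statistic("tajima_d", 25, null)
  p <- simulate_pvalue("tajima_d", stats::median(d), 25, S = 15, reps = 3000)
  expect_close(p, 0.5, 0.04)
  expect_true(is.na(simulate_pvalue("tajima_d", NA_real_, 10, S = 5)))
})

test_that("the coalescent null simulator has the right first moments", {
  set.seed(17)
  n <- 12; theta <- 4
  sim <- coalescent_null_stats(n, 6000, theta = theta)
  an <- sum(1 / (1:(n - 1)))
  expect_close(mean(sim[, "S"]), an * theta, 3 * sd(sim[, "S"]) / sqrt(6000))
  expect_close(mean(sim[, "pi"]), theta, 3 * sd(sim[, "pi"]) / sqrt(6000))
  # conditioned on S the count is exact
  simS <- coalescent_null_stats(n, 200, S = 7)
  expect_true(all(simS[, "S"] == 7))
})
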