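test_that("the demographic model and its intensity integral are coherent", {
  m <- demographic_model(1000, 0.01, 200)
  expect_equal(pop_size_at(m, 300), 1000)
  expect_equal(pop_size_at(m, 0), 1000 * exp(0.01 * 200))
  expect_gt(pop_size_at(m, 50), pop_size_at(m, 150))  # growth toward present
  # integral of 1/N over a growth + constant span, against numeric quadrature
  ii <- uniparent:::intensity_integral(m, 50, 400)
  num <- stats::integrate(function(t) 1 / pop_size_at(m, t), 50, 400,
                          subdivisions = 500L)$value
  expect_equal(ii, num, tolerance = 1e-4)  # quadrature accuracy
  expect_error(demographic_model(1, 0, 0), "N_anc")
})

test_that("constant-size TMRCAs match coalescent closed forms", {
  set.seed(101)
  mod <- demographic_model(1000)
  t2 <- sim_tmrca(2, mod, 8000)
  se2 <- stats::sd(t2) / sqrt(length(t2))
  expect_close(mean(t2), 1000, 3 * se2)          # E[T2] = N
  t10 <- sim_tmrca(10, mod, 8000)
  se10 <- stats::sd(t10) / sqrt(length(t10))
  expect_close(mean(t10), 2 * 1000 * (1 - 1 / 10), 3 * se10)  # 2N(1-1/n)
})

test_that("growth compresses recent branches: TMRCA exceeds the onset", {
  set.seed(55)
  mod <- demographic_model(500, alpha = 5, t_onset = 100)  # explosive growth
  t <- sim_tmrca(6, mod, 400)
  expect_true(all(t > 100))
  expect_lt(stats::median(t) - 100, 500 * 4)  # ancestral phase dominates
})

test_that("simulate_tree produces valid ultrametric genealogies", {
  set.seed(2)
  tr <- simulate_tree(9, demographic_model(800, 0.005, 150))
  expect_equal(length(tr$parent), 17L)
  expect_equal(sum(tr$parent == 0), 1L)           # one root
  for (v in 1:16) expect_gt(tr$times[tr$parent[v]], tr$times[v] - 1e-12)
  expect_true(all(tr$times[1:9] == 0))
})

test_that("the SMM mutation engine matches its variance identity", {
  mu <- 0.002; T <- 500
  tree <- structure(list(n = 2L, parent = c(3L, 3L, 0L),
                         times = c(0, 0, T)), class = "coalescent_tree")
  set.seed(10)
  d2 <- replicate(4000, {
    h <- mutate_strs(tree, c(L1 = mu))
    (h[1, 1] - h[2, 1])^2
  })
  se <- stats::sd(d2) / sqrt(length(d2))
  expect_close(mean(d2), 2 * mu * T, 3 * se)     # E[ASD] = mu * 2T over 2T
  # zero rates: everyone equals the root
  h0 <- mutate_strs(tree, c(L1 = 0, L2 = 0))
  expect_true(all(h0 == 14L))
  # schema: n x loci integer table
  tr <- simulate_tree(20, demographic_model(500), seed = 3)
  h <- mutate_strs(tr, mutation_rates("OMRB"), seed = 4)
  expect_equal(dim(h), c(20L, 15L))
  expect_false(any(c("DYS385a", "DYS385b") %in% colnames(h)))
  expect_true(all(h >= 5 & h <= 40))
})

test_that("asd_tmrca is unbiased on stars and exactly linear in 1/mu", {
  rates <- c(A = 0.002, B = 0.002, C = 0.002)
  founder <- c(A = 14L, B = 14L, C = 14L)
  expect_equal(asd_tmrca(matrix(14L, 6, 3, dimnames = list(NULL, names(rates))),
                         rates, founder), 0)
  set.seed(33)
  Tg <- 1000; n <- 40; reps <- 300
  est <- replicate(reps, {
    h <- vapply(names(rates), function(l) {
      k <- stats::rpois(n, rates[[l]] * Tg)
      14L + vapply(k, function(kk)
        if (kk == 0) 0L else sum(sample(c(-1L, 1L), kk, TRUE)), 0L)
    }, integer(n))
    asd_tmrca(h, rates, founder)
  })
  se <- stats::sd(est) / sqrt(reps)
  expect_close(mean(est), Tg * 25, 3 * se)
  # doubling mu halves the estimate on fixed data
  h <- matrix(c(14L, 16L, 13L, 15L, 14L, 12L), 2, 3,
              dimnames = list(NULL, names(rates)))
  expect_equal(asd_tmrca(h, rates * 2, founder),
               asd_tmrca(h, rates, founder) / 2)
})

test_that("the SMM pruning likelihood agrees with direct enumeration", {
  # two leaves, known branch lengths: likelihood = sum_root pi(r) *
  # P(r -> a1) P(r -> a2), computable from the lattice matrix exponential
  lattice <- uniparent:::smm_lattice(matrix(c(12L, 16L), 1, 2), pad = 6L)
  mu <- 0.003; t1 <- 200; t2 <- 350
  S <- length(lattice$lam)
  P <- function(len) lattice$V %*% diag(exp(lattice$lam * mu * len)) %*%
    t(lattice$V)
  a1 <- 12L - lattice$lo + 1L; a2 <- 16L - lattice$lo + 1L
  direct <- log(sum((1 / S) * P(t1)[, a1] * P(t2)[, a2]))
  tree <- structure(list(n = 2L, parent = c(3L, 3L, 0L),
                         times = c(150, 0, 350)), class = "coalescent_tree")
  # branch lengths: leaf1 at time 150 -> 200; leaf2 at 0 -> 350
  states <- matrix(c(12L, 16L), 2, 1) - lattice$lo
  ll <- uniparent:::smm_loglik(tree, states, lattice, mu)
  expect_equal(ll, direct, tolerance = 1e-8)
})

test_that("batwing_mcmc is deterministic under a fixed seed and mixes", {
  set.seed(40)
  tr <- simulate_tree(8, demographic_model(800, 0.01, 200))
  haps <- mutate_strs(tr, stats::setNames(rep(0.002, 5), paste0("L", 1:5)))
  f1 <- suppressWarnings(batwing_mcmc(haps, batwing_priors(), cycles = 400,
                                      burnin = 100, thin = 2, seed = 3))
  f2 <- suppressWarnings(batwing_mcmc(haps, batwing_priors(), cycles = 400,
                                      burnin = 100, thin = 2, seed = 3))
  expect_identical(f1$samples, f2$samples)
  expect_identical(f1$summary, f2$summary)
  expect_equal(nrow(f1$samples), 150L)
  expect_true(all(c("tmrca_years", "expansion_years", "N", "alpha", "mu")
                  %in% names(f1$samples)))
  # degenerate mutation-rate prior is rejected up front
  pr <- batwing_priors(); pr$mu_shape <- 0
  expect_error(batwing_mcmc(haps, pr), "positive mean")
})
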