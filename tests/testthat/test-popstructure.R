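test_that("frequency tables count and normalise per population", {
  asg <- data.frame(population = "DB",
                    haplogroup = c(rep("D1", 8), rep("O3a2c1a", 4),
                                   rep("O2a1", 2), "O3a2c1*", "C*", "J", "R2"))
  ft <- frequency_table(asg)
  expect_equal(unname(rowSums(ft$frequencies)), 1, tolerance = 1e-9)
  expect_equal(haplogroup_percent(ft, "D1", "DB"), 100 * 8 / 18)
  expect_equal(haplogroup_percent(ft, "absent", "DB"), 0)
  expect_error(frequency_table(asg, populations = "XX"), "unknown population")
})

test_that("PCA matches a brute-force eigendecomposition oracle", {
  set.seed(19)
  x <- matrix(stats::runif(60), 10, 6)
  x <- x / rowSums(x)
  pc <- hg_pca(x)
  xc <- scale(x, center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(xc), symmetric = TRUE)$values
  expect_equal(pc$explained_fraction, ev / sum(ev), tolerance = 1e-9)
  # loadings orthonormal
  expect_equal(crossprod(pc$loadings), diag(ncol(pc$loadings)),
               tolerance = 1e-9, ignore_attr = TRUE)
  # scores invariant (up to sign) under row permutation
  perm <- sample(nrow(x))
  pc2 <- hg_pca(x[perm, ])
  for (j in 1:3) {
    a <- pc$scores[perm, j]; b <- pc2$scores[, j]
    expect_true(max(abs(a - b)) < 1e-8 || max(abs(a + b)) < 1e-8)
  }
  # rank-1 cline: PC1 explains everything
  cline <- cbind(c(0.2, 0.5, 0.8), 1 - c(0.2, 0.5, 0.8))
  pcc <- hg_pca(cline)
  expect_equal(pcc$explained_fraction[1], 1, tolerance = 1e-9)
  # identical populations: degenerate signal
  expect_true(hg_pca(matrix(0.5, 4, 2))$degenerate)
})

test_that("R_ST behaves at the boundaries and under a variance model", {
  h <- rbind(matrix(10L, 5, 3), matrix(c(15L, 10L, 10L), 5, 3, byrow = TRUE))
  colnames(h) <- paste0("L", 1:3)
  pops <- rep(c("p1", "p2"), each = 5)
  dm <- pairwise_str_distance(h, pops)
  expect_equal(dm$d["p1", "p2"], 1)              # fixed difference, no within
  expect_equal(diag(dm$d), c(0, 0), ignore_attr = TRUE)
  expect_equal(dm$d, t(dm$d))
  # identical populations -> 0
  dm0 <- pairwise_str_distance(rbind(h[1:5, ], h[1:5, ]), pops)
  expect_equal(dm0$d["p1", "p2"], 0)
  expect_error(pairwise_str_distance(h, rep("p", 10)), "two populations")
  # additive variance model: E[R_ST] ~= sb/(sb+sw)
  set.seed(23)
  reps <- 300; target <- 0.1
  sw <- 1; sb <- sw * target / (1 - target)
  est <- replicate(reps, {
    mu1 <- stats::rnorm(2, 14, sqrt(sb)); mu2 <- stats::rnorm(2, 14, sqrt(sb))
    g <- rbind(cbind(stats::rnorm(25, mu1[1], sqrt(sw)),
                     stats::rnorm(25, mu1[2], sqrt(sw))),
               cbind(stats::rnorm(25, mu2[1], sqrt(sw)),
                     stats::rnorm(25, mu2[2], sqrt(sw))))
    g <- round(pmin(pmax(g, 5), 40))
    colnames(g) <- c("L1", "L2")
    pairwise_str_distance(g, rep(c("a", "b"), each = 25))$d[1, 2]
  })
  se <- stats::sd(est) / sqrt(reps)
  expect_close(mean(est), target, 3 * se + 0.01)  # rounding bias allowance
  # haplotype-identity mode
  dmf <- pairwise_str_distance(h, pops, mode = "fst")
  expect_gt(dmf$d["p1", "p2"], 0)
})

test_that("neighbour joining recovers additive distances exactly", {
  m <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- neighbor_joining(m)
  # topology AB|CD and branch lengths {1,2,3,4,1} from ((A:1,B:2):1,(C:3,D:4))
  expect_s3_class(tr, "phylo")
  expect_setequal(round(tr$edge.length, 9), c(1, 2, 3, 4, 1))
  d2 <- ape::cophenetic.phylo(tr)[rownames(m), colnames(m)]
  expect_equal(d2, m, tolerance = 1e-9, ignore_attr = TRUE)
  # order invariance
  perm <- c("C", "A", "D", "B")
  tr2 <- neighbor_joining(m[perm, perm])
  expect_equal(ape::cophenetic.phylo(tr2)[rownames(m), colnames(m)], m,
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(neighbor_joining(matrix(c(0, NA, NA, 0), 2, 2)), "non-finite")
  # property: random additive (ultrametric-free) trees are recovered
  set.seed(31)
  for (i in 1:25) {
    nt <- sample(4:8, 1)
    rt <- ape::rtree(nt)
    dd <- ape::cophenetic.phylo(rt)
    rec <- neighbor_joining(dd)
    expect_equal(ape::cophenetic.phylo(rec)[rownames(dd), colnames(dd)], dd,
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  # newick export
  f <- tempfile(fileext = ".nwk")
  write_newick(tr, f)
  expect_true(grepl("^\\(", readLines(f)[1]))
})
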