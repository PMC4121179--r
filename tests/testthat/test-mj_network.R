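test_that("condense merges identical haplotypes with multiplicities", {
  m <- rbind(c(1, 1, 2), c(1, 1, 2), c(1, 2, 2))
  cm <- condense(m, populations = c("a", "b", "a"))
  expect_equal(nrow(cm$states), 2L)
  expect_setequal(cm$multiplicity, c(2L, 1L))
  expect_equal(sum(cm$pop_counts), 3)
  # all distinct: identity
  cm2 <- condense(rbind(c(1, 2), c(2, 1)))
  expect_equal(cm2$multiplicity, c(1L, 1L))
  expect_error(condense(matrix(NA_integer_, 2, 2)), "missing")
})

test_that("the binary triplet {000,110,101} yields the median 100", {
  net <- build_mj(condense(rbind(c(0, 0, 0), c(1, 1, 0), c(1, 0, 1))))
  expect_equal(nrow(net$nodes), 4L)
  expect_true(any(apply(net$nodes, 1, paste, collapse = "") == "100"))
  expect_equal(sum(net$median), 1L)
  expect_equal(network_length(net), 3)
  expect_true(all(net$edges$weight == 1))
})

test_that("degenerate inputs give the expected minimal networks", {
  # two haplotypes at distance 1: single edge, no medians
  net <- build_mj(condense(rbind(c(0, 0), c(0, 1))))
  expect_equal(nrow(net$edges), 1L)
  expect_equal(sum(net$median), 0L)
  # star input: founder hub, no medians
  star <- rbind(c(5, 5, 5), c(6, 5, 5), c(5, 6, 5), c(5, 5, 6), c(4, 5, 5))
  ns <- build_mj(condense(star))
  expect_equal(sum(ns$median), 0L)
  expect_equal(nrow(ns$edges), 4L)
  deg <- tabulate(c(ns$edges$from, ns$edges$to), nbins = 5)
  expect_equal(max(deg), 4L)  # the founder is the hub
})

test_that("epsilon relaxation only adds structure; lengths never beat Steiner", {
  set.seed(4)
  for (i in 1:25) {
    nt <- sample(3:5, 1); nc <- sample(3:6, 1)
    obs <- unique(matrix(sample(0:1, nt * nc, TRUE), ncol = nc))
    if (nrow(obs) < 3) next
    cm <- condense(obs)
    n0 <- build_mj(cm, epsilon = 0)
    n1 <- build_mj(cm, epsilon = 1)
    # monotonicity: every epsilon=0 edge (as a node-state pair) appears in
    # the epsilon=1 network
    key <- function(net, e) paste(
      paste(net$nodes[net$edges$from[e], ], collapse = ""),
      paste(net$nodes[net$edges$to[e], ], collapse = ""))
    k0 <- vapply(seq_len(nrow(n0$edges)), function(e) key(n0, e), "")
    k1 <- vapply(seq_len(nrow(n1$edges)), function(e) key(n1, e), "")
    k1r <- c(k1, vapply(seq_len(nrow(n1$edges)), function(e) paste(
      strsplit(k1[e], " ")[[1]][2], strsplit(k1[e], " ")[[1]][1]), ""))
    expect_true(all(k0 %in% k1r))
    # network length bounded by observed MST above, Steiner minimum below
    mstlen <- uniparent:::mst_length(obs, rep(1, nc))
    stein <- steiner_min_length(obs, max_extra = 2)
    for (net in list(n0, n1)) {
      expect_lte(network_length(net), mstlen)
      expect_gte(network_length(net), stein - 1e-9)
    }
  }
})

test_that("STR data use the weighted single-step distance", {
  m <- rbind(c(14, 10), c(16, 10), c(14, 11))
  cm <- condense(m, weights = c(1, 2))
  net <- build_mj(cm)
  expect_equal(sort(net$edges$weight), c(2, 2))
  # median generation blow-up guard
  expect_error(build_mj(condense(rbind(c(0, 0, 0), c(1, 1, 0), c(1, 0, 1))),
                        max_medians = 0),
               "latent nodes")
})

test_that("networks export to igraph/GML with annotations", {
  m <- rbind(c(0, 0, 0), c(1, 1, 0), c(1, 0, 1))
  net <- build_mj(condense(m, populations = c("p1", "p1", "p2")))
  g <- as_igraph(net)
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_equal(sum(igraph::V(g)$median), 1)
  f <- tempfile(fileext = ".gml")
  write_network_gml(net, f)
  expect_true(file.exists(f) && file.size(f) > 0)
})
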