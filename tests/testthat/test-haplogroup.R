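test_that("assign_y reproduces hierarchical panel classification", {
  tree <- y_panel_tree()
  # D1: derived M168 > M174 > M15, intermediate markers untyped
  a <- assign_y(y_profile_with(c("M168", "M174", "M15")), tree)
  expect_equal(a$haplogroup, "D1")
  expect_equal(a$score, 3L)
  # C*: M130 derived, all typed subclade markers ancestral
  a2 <- assign_y(y_profile_with("M130",
                                ancestral = c("M105", "M38", "M217",
                                              "M347", "M356")), tree)
  expect_equal(a2$haplogroup, "C*")
  # all ancestral -> unresolved
  a3 <- assign_y(y_profile_with(character(0), default = "ancestral"), tree)
  expect_equal(a3$haplogroup, "unresolved")
  # derived states on mutually exclusive branches -> conflict error
  expect_error(assign_y(y_profile_with(c("M168", "M174", "M130")), tree),
               "conflict.*M")
})

test_that("assign_y is monotone in derived path markers", {
  tree <- y_panel_tree()
  yd <- generate_y_dataset(study_design("y"), seed = 21, mask_fraction = 0.5)
  depth_of <- function(hg) length(uniparent:::tree_path(tree, sub("\\*$", "", hg)))
  for (p in yd$profiles[seq(1, length(yd$profiles), by = 7)]) {
    a <- assign_y(p, tree)
    if (a$haplogroup == "unresolved") next
    node <- sub("\\*$", "", a$haplogroup)
    # type one untyped marker below/above on the true path as derived
    truth <- yd$truth$haplogroup[yd$truth$sample_id == p$sample_id]
    path <- uniparent:::tree_path(tree, sub("\\*$", "", truth))
    path_markers <- unlist(lapply(path, function(x) tree$nodes[[x]]$variants))
    untyped <- path_markers[p$snp_states[path_markers] == "untyped"]
    if (!length(untyped)) next
    p2 <- p; p2$snp_states[untyped[1]] <- "derived"
    a2 <- assign_y(p2, tree)
    expect_gte(depth_of(a2$haplogroup), depth_of(a$haplogroup))
  }
})

test_that("assign_mt scores HVS-I motifs with coding anchors and reports ties", {
  tree <- mt_subtree()
  cd <- c("7600" = "derived", "10400" = "derived", "4833" = "derived")
  a <- assign_mt(hvs1_sequence("x", "P", "16223-16227-16278-16362"), cd, tree)
  expect_equal(a$haplogroup, "G2a")
  # reference-identical sample with no derived coding SNPs -> tree root
  a2 <- assign_mt(hvs1_sequence("x", "P", ""),
                  c("10400" = "ancestral", "10873" = "ancestral"), tree)
  expect_equal(a2$haplogroup, tree$root)
  expect_false(a2$tied)
  # simultaneous G2a (16278) and G3 (16274) signals: reported as a tie
  a3 <- assign_mt(hvs1_sequence("x", "P", "16223-16274-16278"), NULL, tree)
  expect_true(a3$tied)
  expect_setequal(a3$candidates, c("G2a", "G3"))
  expect_error(assign_mt(hvs1_sequence("x", "P", ""), NULL,
                         haplogroup_tree(stats::setNames(list(), character(0)))),
               "root|empty")
})

test_that("tree fixtures are well-formed and read back from JSON", {
  yt <- y_panel_tree(); mt <- mt_subtree()
  for (tr in list(yt, mt)) {
    expect_s3_class(tr, "haplogroup_tree")
    nonroot <- setdiff(names(tr$nodes), tr$root)
    for (nm in nonroot)
      expect_gt(length(c(tr$nodes[[nm]]$variants, tr$nodes[[nm]]$coding)), 0)
  }
  expect_true(is_ancestor(mt, "M", "D4j3"))
  expect_false(is_ancestor(mt, "G", "D4"))
  expect_equal(macrohaplogroup(mt, c("D4j3", "F1a", "G2a", "A4*")),
               c("M", "N", "M", "N"), ignore_attr = TRUE)
})

test_that("generated datasets are recovered as the true clade or an ancestor", {
  ytree <- y_panel_tree(); mtree <- mt_subtree()
  yd <- generate_y_dataset(study_design("y"), seed = 5)
  cls <- classify_y(yd$profiles, ytree)
  expect_identical(cls$haplogroup, yd$truth$haplogroup)  # complete typing
  # 50% masking: true clade or an ancestor in >= 99% of cases
  ydm <- generate_y_dataset(study_design("y"), seed = 6, mask_fraction = 0.5)
  clsm <- classify_y(ydm$profiles, ytree)
  ok <- mapply(function(a, t) {
    a == t || is_ancestor(ytree, a, t) || a == "unresolved"
  }, clsm$haplogroup, ydm$truth$haplogroup)
  expect_gte(mean(ok), 0.99)
  md <- generate_mt_dataset(study_design("mt"), seed = 5)
  cm <- classify_mt(md$seqs, mtree, coding = md$coding)
  okm <- mapply(function(a, t) a == t || is_ancestor(mtree, a, t),
                cm$haplogroup, md$truth$haplogroup)
  expect_gte(mean(okm), 0.99)
})
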