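# caterpillar with two outgroups: clade {a..e} has 4 internal nodes
caterpillar <- function() {
  ape::read.tree(text = "((((((a,b),c),d),e),o1),o2);")
}

clade_profile <- function(supports) {
  tr <- caterpillar()
  taxa <- sort(tr$tip.label)
  keys <- c(ab = split_key(c("a", "b"), taxa),
            abc = split_key(c("a", "b", "c"), taxa),
            abcd = split_key(c("a", "b", "c", "d"), taxa),
            abcde = split_key(c("a", "b", "c", "d", "e"), taxa))
  support_profile("x", tr,
                  stats::setNames(supports, unname(keys)),
                  clade_taxa = c("a", "b", "c", "d", "e"))
}

split_key <- phylodegen:::split_key

test_that("internal-node counts follow the rooted-subtree convention", {
  tr <- caterpillar()
  expect_identical(count_internal_nodes(tr, c("a", "b", "c", "d", "e")), 4L)
  expect_identical(count_internal_nodes(tr, c("a", "b", "c")), 2L)
  expect_identical(count_internal_nodes(tr, c("a", "b")), 1L)
  expect_identical(count_internal_nodes(simulate_tree(52, seed = 2)), 51L)
  poly <- ape::read.tree(text = "((a,b,c),d);")
  expect_warning(n <- count_internal_nodes(poly, c("a", "b", "c")),
                 "not fully bifurcating")
  expect_identical(n, 1L)
})

test_that("threshold fractions count nodes at or above each cutoff", {
  prof <- clade_profile(c(95, 85, 75, 60))
  rep <- threshold_fractions(prof, c(70, 80, 90))
  expect_identical(rep$n_nodes, 4L)
  expect_identical(unname(rep$n_meeting), c(3L, 2L, 1L))
  expect_identical(unname(rep$fraction_percent), c(75, 50, 25))
})

test_that("all-maximal supports give 100% at every threshold", {
  prof <- clade_profile(c(100, 100, 100, 100))
  rep <- threshold_fractions(prof, c(70, 80, 90))
  expect_true(all(rep$fraction_percent == 100))
})

test_that("fractions are non-increasing in the threshold", {
  set.seed(81)
  for (i in 1:10) {
    prof <- clade_profile(stats::runif(4, 0, 100))
    rep <- threshold_fractions(prof, c(50, 70, 80, 90, 99))
    expect_true(all(diff(rep$fraction_percent) <= 0))
    # every strong node is also moderate-or-better
    expect_lte(rep$n_meeting[which(rep$thresholds == 80)],
               rep$n_meeting[which(rep$thresholds == 70)])
  }
})

test_that("artifact detection flags only strong splits absent from reduced", {
  tr <- caterpillar()
  taxa <- sort(tr$tip.label)
  full_sup <- stats::setNames(c(95, 85), c(split_key(c("a", "b"), taxa),
                                           split_key(c("a", "b", "c"), taxa)))
  full <- support_profile("full", tr, full_sup)
  # identical trees: nothing to flag regardless of support
  red_same <- support_profile("red", tr, full_sup)
  expect_length(detect_missing_data_artifacts(full, red_same, 80), 0L)
  # reduced tree lacking the (a,b,c) clade: that split is an artifact signal
  red_tree <- ape::read.tree(text = "((((((a,b),d),c),e),o1),o2);")
  red <- support_profile("red", red_tree, stats::setNames(numeric(0),
                                                          character(0)))
  art <- detect_missing_data_artifacts(full, red, 80)
  expect_identical(names(art), split_key(c("a", "b", "c"), taxa))
  # below-threshold or present splits are not reported
  art90 <- detect_missing_data_artifacts(full, red, 90)
  expect_length(art90, 0L)
  bad <- support_profile("bad", ape::rtree(5), NULL)
  expect_error(detect_missing_data_artifacts(full, bad, 80), "taxon set")
})

test_that("coding comparison tables mark absent nodes with '-'", {
  tr <- caterpillar()
  taxa <- sort(tr$tip.label)
  k_ab <- split_key(c("a", "b"), taxa)
  k_abc <- split_key(c("a", "b", "c"), taxa)
  p1 <- support_profile("nt123", tr,
                        stats::setNames(c(99, 88), c(k_ab, k_abc)))
  alt <- ape::read.tree(text = "((((((a,b),d),c),e),o1),o2);")
  p2 <- support_profile("degen1", alt, stats::setNames(77, k_ab))
  tab <- compare_codings(list(p1, p2))
  expect_identical(names(tab), c("split", "nt123", "degen1"))
  expect_identical(tab$nt123[tab$split == k_abc], "88")
  expect_identical(tab$degen1[tab$split == k_abc], "-")
  expect_identical(tab$degen1[tab$split == k_ab], "77")
  # single profile reproduces its own supports
  tab1 <- compare_codings(list(p1))
  expect_identical(tab1$nt123[tab1$split == k_ab], "99")
})

test_that("split keys are invariant to rotation and leaf order", {
  tr <- simulate_tree(9, seed = 82)
  tru <- ape::unroot(tr)
  rot <- ape::rotateConstr(tru, rev(tru$tip.label))
  expect_setequal(tree_splits(tru), tree_splits(rot))
  reroot <- ape::unroot(ape::root(tru, outgroup = tru$tip.label[5],
                                  resolve.root = TRUE))
  expect_setequal(tree_splits(tru), tree_splits(reroot))
})
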