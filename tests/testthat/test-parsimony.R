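test_that("Fitch score matches textbook cases", {
  tr12 <- parse_newick("((t1,t2),(t3,t4));")
  tr13 <- parse_newick("((t1,t3),(t2,t4));")
  aln <- phy_alignment(c(t1 = "1", t2 = "1", t3 = "2", t4 = "2"),
                       alphabet_dayhoff6())
  expect_equal(fitch_score(tr12, aln), 1L)
  expect_equal(fitch_score(tr13, aln), 2L)
  inv <- phy_alignment(c(t1 = "3", t2 = "3", t3 = "3", t4 = "3"),
                       alphabet_dayhoff6())
  expect_equal(fitch_score(tr12, inv), 0L)
  gap <- phy_alignment(c(t1 = "X", t2 = "-", t3 = "?", t4 = "X"),
                       alphabet_dayhoff6())
  expect_equal(fitch_score(tr12, gap), 0L)
})

test_that("Fitch score equals the exhaustive minimum-change oracle", {
  set.seed(3)
  for (rep in 1:3) {
    tr <- ape::unroot(ape::rtree(6))
    aln <- random_aln(tr$tip.label, 30, alphabet_dayhoff6(),
                      seed = 100 + rep)
    aln$seq[sample(length(aln$seq), 12)] <- "X"
    expect_equal(fitch_score(tr, aln), brute_parsimony(tr, aln))
  }
})

test_that("Fitch score agrees with an independent implementation", {
  set.seed(5)
  tr <- ape::unroot(ape::rtree(8))
  aln <- random_aln(tr$tip.label, 80, alphabet_dayhoff6(), seed = 7)
  pd <- phangorn::phyDat(aln$seq, type = "USER",
                         levels = as.character(1:6),
                         ambiguity = c("X", "-", "?"))
  expect_equal(fitch_score(tr, aln),
               as.integer(phangorn::fitch(tr, pd)))
})

test_that("Fitch score is invariant to rooting and child order", {
  set.seed(8)
  tr <- ape::unroot(ape::rtree(7))
  aln <- random_aln(tr$tip.label, 40, alphabet_dayhoff6(), seed = 9)
  ref <- fitch_score(tr, aln)
  for (tip in tr$tip.label[1:4]) {
    rr <- ape::root(tr, outgroup = tip, resolve.root = TRUE)
    expect_equal(fitch_score(rr, aln), ref)
  }
  expect_equal(fitch_score(ape::rotateConstr(tr, rev(sort(tr$tip.label))),
                           aln), ref)
})

test_that("concatenation score is the sum of per-partition scores", {
  set.seed(10)
  tr <- ape::unroot(ape::rtree(6))
  a1 <- random_aln(tr$tip.label, 25, alphabet_dayhoff6(), seed = 11)
  a2 <- random_aln(tr$tip.label, 35, alphabet_dayhoff6(), seed = 12)
  both <- phy_alignment(cbind(a1$seq, a2$seq), alphabet_dayhoff6())
  expect_equal(fitch_score(tr, both),
               fitch_score(tr, a1) + fitch_score(tr, a2))
})

test_that("NNI search is monotone and stationary at an optimum", {
  fx <- backbone_fixture("T1")
  m6 <- model_dayhoff6()
  aln <- simulate_alignment(fx$tree, m6, 400, seed = 13)
  true_score <- fitch_score(fx$tree, aln)
  res <- parsimony_search_nni(aln, fx$tree, seed = 2)
  expect_equal(attr(res, "score"), true_score)   # already optimal here
  expect_true(all(diff(attr(res, "trajectory")) <= 0))
  rand <- ape::rtree(11, rooted = FALSE,
                     tip.label = sample(fx$tree$tip.label))
  res2 <- parsimony_search_nni(aln, rand, seed = 3)
  expect_true(all(diff(attr(res2, "trajectory")) <= 0))
  expect_lte(attr(res2, "score"), fitch_score(rand, aln))
})

test_that("jackknife support is reproducible and saturates on clean data", {
  fx <- backbone_fixture("T1", internal_bl = 0.15)
  m6 <- model_dayhoff6()
  aln <- simulate_alignment(fx$tree, m6, 600, seed = 14)
  sup <- jackknife_support(aln, deletion = 0.01, replicates = 15L,
                           seed = 4, n_starts = 4L)
  expect_true(all(sup$support >= 0 & sup$support <= 100))
  sup2 <- jackknife_support(aln, deletion = 0.01, replicates = 15L,
                            seed = 4, n_starts = 4L)
  expect_identical(sup$support, sup2$support)
  ## near-zero deletion: replicates see almost the full matrix
  expect_gte(stats::median(sup$support), 90)
  expect_error(jackknife_support(aln, deletion = 1.2, replicates = 2L, 1),
               "deletion")
})
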