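test_that("parse_newick handles minimal trees and preserves path lengths", {
  t2 <- parse_newick("(A,B);")
  expect_s3_class(t2, "phylo")
  expect_setequal(t2$tip.label, c("A", "B"))
  expect_equal(t2$Nnode, 1L)

  t3 <- parse_newick("((A:1.0,B:1.0):0.5,C:1.0);")
  expect_equal(length(t3$tip.label), 3L)
  d <- ape::cophenetic.phylo(t3)
  expect_equal(d["A", "C"], 2.5)
})

test_that("malformed newick is rejected with an offset, duplicates rejected", {
  expect_error(parse_newick("((A,B);"), "unbalanced")
  expect_error(parse_newick("(A,B)"), "offset")
  expect_error(parse_newick("(A,(B,A));"), "duplicate")
  expect_error(parse_newick("(A:1,B:-0.5);"), "finite")
})

test_that("write/parse round-trip reproduces the same splits", {
  set.seed(7)
  for (rep in 1:3) {
    tr <- ape::rtree(20)
    back <- parse_newick(write_newick(tr))
    expect_equal(rf_distance(tr, back), 0L)
    expect_setequal(tree_splits(tr), tree_splits(back))
  }
})

test_that("restrict_to_taxa prunes and suppresses degree-2 nodes", {
  tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  sub <- restrict_to_taxa(tr, c("A", "B", "C"))
  expect_setequal(sub$tip.label, c("A", "B", "C"))
  expect_true(ape::is.monophyletic(sub, c("A", "B")))
  ## pruned path from C absorbs the suppressed node's branch
  expect_equal(ape::cophenetic.phylo(sub)["A", "C"], 4)

  expect_equal(rf_distance(restrict_to_taxa(tr, tr$tip.label), tr), 0L)
  expect_error(restrict_to_taxa(tr, c("A", "Z")), "Z")
})

test_that("restriction agrees with the induced-split oracle on a caterpillar", {
  tr <- parse_newick("(((((((A:1,B:1):1,C:1):1,D:1):1,E:1):1,F:1):1,G:1):1,H:1);")
  keep <- c("A", "C", "E", "G", "H")
  sub <- restrict_to_taxa(tr, keep)
  ## oracle: restrict every split of the full tree, discard trivial ones
  anchor <- sort(keep)[1L]
  induced <- unique(vapply(tree_splits(tr), function(k) {
    side <- intersect(strsplit(k, "|", fixed = TRUE)[[1L]], keep)
    if (length(side) < 2L || length(side) > length(keep) - 2L)
      return(NA_character_)
    if (anchor %in% side) side <- setdiff(keep, side)
    if (length(side) < 2L) return(NA_character_)
    paste(sort(side), collapse = "|")
  }, character(1L)))
  induced <- induced[!is.na(induced)]
  expect_setequal(tree_splits(sub), induced)
})

test_that("restriction commutes with relabeling", {
  set.seed(11)
  tr <- ape::rtree(10)
  relab <- setNames(paste0("X", seq_len(10)), tr$tip.label)
  tr2 <- tr
  tr2$tip.label <- unname(relab[tr$tip.label])
  keep <- tr$tip.label[c(1, 3, 5, 7, 9)]
  a <- restrict_to_taxa(tr, keep)
  a$tip.label <- unname(relab[a$tip.label])
  b <- restrict_to_taxa(tr2, unname(relab[keep]))
  expect_equal(rf_distance(a, b), 0L)
})

test_that("topology enumeration has (2n-5)!! distinct members", {
  expect_length(enumerate_unrooted_topologies(LETTERS[1:4]), 3L)
  expect_length(enumerate_unrooted_topologies(LETTERS[1:5]), 15L)
  all6 <- enumerate_unrooted_topologies(LETTERS[1:6])
  expect_length(all6, 105L)
  dd <- as.matrix(phangorn::RF.dist(all6))
  expect_true(all(dd[upper.tri(dd)] > 0))
  expect_error(enumerate_unrooted_topologies(LETTERS[1:3]), "4..9")
  expect_error(enumerate_unrooted_topologies(LETTERS[1:10]), "4..9")
})

test_that("rf_distance matches the split-set symmetric difference oracle", {
  tr <- parse_newick("((A,B),(C,D));")
  t2 <- parse_newick("((A,C),(B,D));")
  expect_equal(rf_distance(tr, tr), 0L)
  expect_equal(rf_distance(tr, t2), 2L)
  expect_error(rf_distance(tr, parse_newick("((A,B),(C,E));")), "tip set")
  set.seed(5)
  for (rep in 1:5) {
    a <- ape::rtree(10)
    b <- ape::rtree(10)
    sym <- length(setdiff(tree_splits(a), tree_splits(b))) +
      length(setdiff(tree_splits(b), tree_splits(a)))
    expect_equal(rf_distance(a, b), sym)
  }
})

test_that("rf_distance behaves as a metric on random triples", {
  set.seed(9)
  for (rep in 1:5) {
    trees <- replicate(3, ape::rtree(8), simplify = FALSE)
    d12 <- rf_distance(trees[[1]], trees[[2]])
    d13 <- rf_distance(trees[[1]], trees[[3]])
    d23 <- rf_distance(trees[[2]], trees[[3]])
    expect_equal(d12, rf_distance(trees[[2]], trees[[1]]))
    expect_true(d13 <= d12 + d23)
  }
})

test_that("clade constraints are evaluated as splits on any rooting", {
  t2 <- backbone_fixture("T2")$tree
  t1 <- backbone_fixture("T1")$tree
  con <- clade_constraint(c("Chrysomyinae", "Luciliinae", "Calliphorinae",
                            "Toxotarsinae"))
  expect_true(satisfies_constraints(t2, con))
  expect_false(satisfies_constraints(t1, con))
  expect_true(satisfies_constraints(t1, clade_constraint(t1$tip.label)))
  expect_error(satisfies_constraints(t1, clade_constraint(c("A", "B"))),
               "not in tree")
})
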