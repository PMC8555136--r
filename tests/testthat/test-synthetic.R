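test_that("zero branch lengths copy the root state to every taxon", {
  tr <- parse_newick("((A:0,B:0):0,(C:0,D:0):0);")
  aln <- simulate_alignment(tr, model_jc(), 50, seed = 2)
  expect_true(all(apply(aln$seq, 2, function(col) length(unique(col)) == 1L)))
})

test_that("two-taxon divergence matches the JC closed form", {
  tr <- parse_newick("(A:0.15,B:0.15);")   # path length 0.3
  n <- 30000
  aln <- simulate_alignment(tr, model_jc(), n, seed = 3)
  p <- mean(aln$seq["A", ] != aln$seq["B", ])
  expected <- 3 / 4 * (1 - exp(-4 * 0.3 / 3))
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(p - expected), 3 * se)
})

test_that("simulation is a pure function of inputs and seed", {
  tr <- backbone_fixture("T1")$tree
  m <- model_poisson(alpha = 0.8, ncat = 4L)
  a1 <- simulate_alignment(tr, m, 100, seed = 42)
  a2 <- simulate_alignment(tr, m, 100, seed = 42)
  expect_identical(a1$seq, a2$seq)
  expect_false(identical(a1$seq, simulate_alignment(tr, m, 100, 43)$seq))
})

test_that("supermatrix completeness reflects the missing-data pattern", {
  tr <- backbone_fixture("T1")$tree
  m <- model_poisson()
  full <- lapply(1:10, function(i) gene_spec(paste0("g", i), 20L))
  sm <- simulate_supermatrix(tr, full, m, seed = 4)
  expect_equal(completeness_ca(sm$alignment), 1.0)
  expect_equal(nrow(sm$partitions), 10L)
  expect_equal(sm$partitions$end[10L], 200L)

  taxa <- tr$tip.label
  half <- lapply(1:6, function(i)
    gene_spec(paste0("h", i), 20L,
              missing = taxa[seq(1L + i %% 2L, length(taxa), by = 2L)]))
  smh <- simulate_supermatrix(tr, half, m, seed = 5)
  expect_equal(completeness_ca(smh$alignment),
               mean(vapply(half, function(g)
                 1 - length(g$missing) / length(taxa), numeric(1L))),
               tolerance = 1e-12)
  expect_error(simulate_supermatrix(tr, list(gene_spec("bad", 10L,
                                                       missing = taxa)),
                                    m, 1), "missing all taxa")
})

test_that("per-gene rate multipliers scale recovered distances", {
  m <- model_jc()
  tr <- parse_newick("(A:0.05,B:0.05);")   # base path 0.1
  genes <- list(gene_spec("slow", 20000L, rate = 0.5),
                gene_spec("fast", 20000L, rate = 2.0))
  sm <- simulate_supermatrix(tr, genes, m, seed = 6)
  est <- vapply(split_supermatrix(sm$alignment, sm$partitions), function(a) {
    p <- mean(a$seq["A", ] != a$seq["B", ])
    -3 / 4 * log(1 - 4 * p / 3)
  }, numeric(1L))
  expect_gt(est[["fast"]] / est[["slow"]], 3.3)
  expect_lt(est[["fast"]] / est[["slow"]], 4.8)
})

test_that("gene specs emulate the target completeness", {
  specs <- sample_gene_specs(300L, LETTERS[1:20], completeness = 0.7,
                             seed = 8)
  frac <- 1 - mean(vapply(specs, function(g) length(g$missing),
                          numeric(1L))) / 20
  expect_lt(abs(frac - 0.7), 0.03)
})

test_that("MSC gene trees collapse to the species tree without ILS", {
  sp <- parse_newick("((A:1,B:1):50,(C:25,D:25):26);")
  gts <- simulate_gene_trees_msc(sp, 50, seed = 7)
  expect_true(all(vapply(gts, function(g)
    rf_distance(ape::unroot(g), ape::unroot(sp)) == 0, logical(1L))))
  g1 <- simulate_gene_trees_msc(sp, 10, seed = 9)
  g2 <- simulate_gene_trees_msc(sp, 10, seed = 9)
  expect_equal(vapply(g1, write_newick, character(1L)),
               vapply(g2, write_newick, character(1L)))
  expect_error(simulate_gene_trees_msc(ape::unroot(sp), 5, 1), "rooted")
})

test_that("rooted-triple concordance matches 1 - (2/3)exp(-t)", {
  n <- 4000
  sp <- parse_newick("((A:1,B:1):1,C:2);")
  gts <- simulate_gene_trees_msc(sp, n, seed = 10)
  conc <- mean(vapply(gts, function(g)
    ape::is.monophyletic(g, c("A", "B")), logical(1L)))
  expected <- 1 - 2 / 3 * exp(-1)
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(conc - expected), 3 * se)
})

test_that("binary trait simulation honours stationarity and determinism", {
  tr <- parse_newick("((A:0,B:0):0,C:0);")
  sim0 <- simulate_binary_trait(tr, 1, 1, seed = 3)
  expect_equal(length(unique(c(sim0$tip_states, sim0$node_states))), 1L)

  long <- parse_newick("((A:60,B:60):60,C:120);")
  frac <- mean(vapply(1:400, function(s)
    simulate_binary_trait(long, 0.5, 0.5, seed = s)$tip_states[["A"]],
    integer(1L)))
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 400))
  expect_error(simulate_binary_trait(tr, 0, 1, 1), "> 0")
})

test_that("equal-rate trait changes are Poisson with mean rate x length", {
  tr <- parse_newick("(A:2,B:2);")
  q <- 0.5
  n <- 2500
  counts <- vapply(1:n, function(s) {
    sim <- simulate_binary_trait(tr, q, q, seed = s)
    sim$branch_changes[1L]
  }, integer(1L))
  expect_lt(abs(mean(counts) - 1), 3 * sqrt(1 / n))     # Poisson(q*t = 1)
  expect_lt(abs(var(counts) - 1), 0.2)
})

test_that("backbone fixtures encode the three placements of Chrysomyinae", {
  f1 <- backbone_fixture("T1")
  f2 <- backbone_fixture("T2")
  f3 <- backbone_fixture("T3")
  expect_gt(rf_distance(f1$tree, f2$tree), 0)
  expect_gt(rf_distance(f1$tree, f3$tree), 0)
  expect_gt(rf_distance(f2$tree, f3$tree), 0)
  g <- f1$groups
  expect_true(satisfies_constraints(f1$tree, clade_constraint(g$group1)))
  expect_true(satisfies_constraints(
    f2$tree, clade_constraint(c("Chrysomyinae", g$group3))))
  expect_true(satisfies_constraints(
    f3$tree, clade_constraint(c("Chrysomyinae", g$group2b))))
  ## the three trees agree once Chrysomyinae is removed
  keep <- setdiff(f1$tree$tip.label, "Chrysomyinae")
  expect_equal(rf_distance(restrict_to_taxa(f1$tree, keep),
                           restrict_to_taxa(f2$tree, keep)), 0L)
  expect_equal(rf_distance(restrict_to_taxa(f1$tree, keep),
                           restrict_to_taxa(f3$tree, keep)), 0L)
  expect_error(backbone_fixture("T9"))
})
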