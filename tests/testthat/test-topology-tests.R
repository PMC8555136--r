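make_dpl <- function(deltas) {
  df <- data.frame(gene = paste0("g", seq_along(deltas)),
                   pL_T1 = 0, pL_T2 = -deltas)
  df$delta_T1_T2 <- deltas
  structure(df, class = c("delta_pl_table", "data.frame"),
            reference = "T1")
}

test_that("identical trees give an all-zero delta table", {
  fx <- backbone_fixture("T1")
  m <- model_poisson(alpha = 0.8, ncat = 4L)
  sm <- simulate_supermatrix(fx$tree,
                             lapply(1:4, function(i)
                               gene_spec(paste0("g", i), 40L)),
                             m, seed = 3)
  dpl <- per_partition_delta_pl(sm$alignment, sm$partitions,
                                list(T1 = fx$tree, T2 = fx$tree), m,
                                optimize_branches = FALSE)
  expect_true(all(abs(dpl$delta_T1_T2) < 1e-9))
  expect_equal(unname(count_favoring(dpl, c("T1", "T2"))), c(0L, 0L, 4L))
})

test_that("a single-gene matrix reproduces the total likelihood difference", {
  f1 <- backbone_fixture("T1")
  f2 <- backbone_fixture("T2")
  m <- model_poisson(alpha = 0.8, ncat = 4L)
  aln <- simulate_alignment(f1$tree, m, 150, seed = 4)
  parts <- partition_map("only", 150L)
  dpl <- per_partition_delta_pl(aln, parts,
                                list(T1 = f1$tree, T2 = f2$tree), m,
                                optimize_branches = FALSE)
  d_direct <- tree_loglik(f1$tree, aln, m)$loglik -
    tree_loglik(f2$tree, aln, m)$loglik
  expect_equal(dpl$delta_T1_T2[1L], d_direct, tolerance = 1e-9)
})

test_that("delta sums reproduce total differences (additivity)", {
  f1 <- backbone_fixture("T1")
  f2 <- backbone_fixture("T2")
  m <- model_poisson(alpha = 0.8, ncat = 4L)
  sm <- simulate_supermatrix(f1$tree,
                             lapply(1:8, function(i)
                               gene_spec(paste0("g", i), 50L,
                                         rate = 0.5 + 0.2 * i)),
                             m, seed = 6)
  dpl <- per_partition_delta_pl(sm$alignment, sm$partitions,
                                list(T1 = f1$tree, T2 = f2$tree), m)
  totals <- attr(dpl, "totals")
  expect_lt(abs(sum(dpl$delta_T1_T2) - (totals["T1"] - totals["T2"])), 1e-6)
  expect_lt(max(abs(colSums(dpl[, c("pL_T1", "pL_T2")]) - totals)), 1e-6)
})

test_that("count_favoring tallies signs and reports exact ties separately", {
  expect_equal(unname(count_favoring(make_dpl(c(0, 0, 0)), c("T1", "T2"))),
               c(0L, 0L, 3L))
  expect_equal(unname(count_favoring(make_dpl(c(1, -2, 0.5)),
                                     c("T1", "T2"))),
               c(2L, 1L, 0L))
  expect_equal(unname(count_favoring(make_dpl(c(1e-12, -1, 2)),
                                     c("T1", "T2"))),
               c(1L, 1L, 1L))
  expect_error(count_favoring(make_dpl(1), c("T1", "T3")), "not present")
})

test_that("RELL replicates behave like multinomial site resampling", {
  sll <- matrix(-2, 1, 50)
  r <- rell_resample(sll, 1, 20, seed = 1)
  expect_true(all(r == -100))

  set.seed(2)
  sll2 <- rbind(a = rnorm(200, -3), b = rnorm(200, -3.1))
  r2 <- rell_resample(sll2, 0.7, 5000, seed = 3)
  mu <- rowMeans(r2)
  expected <- 0.7 * rowSums(sll2)
  sdr <- apply(r2, 1, sd) / sqrt(5000)
  expect_true(all(abs(mu - expected) < 3 * sdr))

  expect_identical(rell_resample(sll2, 1, 10, seed = 5),
                   rell_resample(sll2, 1, 10, seed = 5))
  expect_error(rell_resample(matrix(0, 0, 0), 1, 10, 1), "empty")
})

test_that("degenerate ties give p_KH = p_SH = 1 and p_AU near 0.5", {
  set.seed(4)
  row <- rnorm(400, -3)
  sll <- rbind(T1 = row, T2 = row)
  rep <- topology_test_suite(sll, replicates = 600, seed = 5)
  expect_equal(rep$p_KH, c(1, 1))
  expect_equal(rep$p_SH, c(1, 1))
  expect_lt(max(abs(rep$p_AU - 0.5)), 0.1)
  expect_true("tie_with_best" %in% rep$flag)
})

test_that("strong simulated signal separates true from wrong topologies", {
  f1 <- backbone_fixture("T1")
  f2 <- backbone_fixture("T2")
  f3 <- backbone_fixture("T3")
  m <- model_poisson(alpha = 0.8, ncat = 4L)
  aln <- simulate_alignment(f1$tree, m, 2000, seed = 11)
  sll <- do.call(rbind, lapply(list(T1 = f1$tree, T2 = f2$tree,
                                    T3 = f3$tree), function(tr)
    tree_loglik(optimize_branch_lengths(tr, aln, m, tol = 1e-3,
                                        max_cycles = 8L),
                aln, m)$site_loglik))
  rep <- topology_test_suite(sll, replicates = 1000, seed = 6)
  expect_equal(rep$tree[rep$delta == 0], "T1")
  expect_gt(rep$p_AU[rep$tree == "T1"], 0.05)
  expect_lt(max(rep$p_AU[rep$tree != "T1"]), 0.05)
  expect_equal(rep$p_KH[rep$tree == "T1"], 1)
  expect_true(all(rep$p_KH >= 0 & rep$p_KH <= 1))
  expect_true(all(rep$p_SH >= rep$p_KH - 1e-9))
})
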