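test_that("two-tip likelihood matches the closed-form 2-state formula", {
  tr <- parse_newick("(A:0.6,B:0.9);")
  trait <- binary_trait(c(A = "0", B = "1"))
  q <- 0.4
  ll <- tree_loglik(tr, flyphy:::.trait_aln(trait, tr$tip.label),
                    model_mk2(q, q))$loglik
  ## P(different | path t) = 1/2 (1 - exp(-2qt)), stationary 1/2 each
  t_tot <- 1.5
  expect_equal(ll, log(0.5 * 0.5 * (1 - exp(-2 * q * t_tot))),
               tolerance = 1e-12)
})

test_that("rescaling branches by c and rates by 1/c leaves lnL unchanged", {
  set.seed(2)
  tr <- ape::rtree(6)
  trait <- binary_trait(setNames(c("1", "0", "1", "0", "1", "?"),
                                 tr$tip.label))
  aln <- flyphy:::.trait_aln(trait, tr$tip.label)
  ll1 <- tree_loglik(tr, aln, model_mk2(0.3, 0.7))$loglik
  tr2 <- tr
  tr2$edge.length <- tr$edge.length * 3
  ll2 <- tree_loglik(tr2, aln, model_mk2(0.1, 0.7 / 3))$loglik
  expect_equal(ll1, ll2, tolerance = 1e-10)
})

test_that("rates are recovered within a factor of two from pooled characters", {
  set.seed(5)
  tr <- ape::rtree(64)
  tr$edge.length <- tr$edge.length * 2
  ## 50 independent characters simulated at q01 = q10 = 0.1, jointly fitted
  ## by summing their log-likelihoods over a shared rate pair
  sims <- lapply(1:50, function(s)
    simulate_binary_trait(tr, 0.1, 0.1, seed = 500 + s)$tip_states)
  alns <- lapply(sims, function(ts)
    flyphy:::.trait_aln(binary_trait(setNames(as.character(ts), names(ts))),
                        tr$tip.label))
  nll <- function(lq) {
    m <- model_mk2(exp(lq[1]), exp(lq[2]))
    -sum(vapply(alns, function(a) tree_loglik(tr, a, m)$loglik,
                numeric(1L)))
  }
  opt <- stats::optim(log(c(0.5, 0.5)), nll, method = "L-BFGS-B",
                      lower = log(1e-4), upper = log(10))
  q_hat <- exp(opt$par)
  expect_true(all(q_hat > 0.05 & q_hat < 0.2))
})

test_that("fit_mk2 rejects monomorphic traits", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  expect_error(fit_mk2(tr, binary_trait(c(A = "1", B = "1", C = "?"))),
               "monomorphic")
})

test_that("marginal probabilities equal joint enumeration on small trees", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(4:6, 1)
    tr <- ape::rtree(n)
    tr$edge.length <- runif(nrow(tr$edge), 0.2, 2)
    states <- sample(c("0", "1", "?"), n, replace = TRUE,
                     prob = c(0.4, 0.4, 0.2))
    states[1:2] <- c("0", "1")
    names(states) <- tr$tip.label
    q01 <- runif(1, 0.05, 1)
    q10 <- runif(1, 0.05, 1)
    m <- marginal_asr(tr, binary_trait(states), q01, q10)
    b <- brute_mk2_marginals(tr, states, q01, q10)
    expect_lt(max(abs(m$prob1 - b[, 2])), 1e-10)
  }
})

test_that("near-zero rates pin every node to a uniform observed state", {
  tr <- ape::rtree(8)
  trait <- binary_trait(setNames(rep("1", 8), tr$tip.label))
  m <- marginal_asr(tr, trait, 1e-6, 1e-6)
  expect_true(all(m$prob1 > 0.999))
})

test_that("mirrored tip states on a symmetric tree mirror the marginals", {
  tr <- parse_newick("((A:1,B:1):0.5,(C:1,D:1):0.5);")
  m1 <- marginal_asr(tr, binary_trait(c(A = "1", B = "1", C = "0",
                                        D = "0")), 0.3, 0.3)
  ab <- m1$prob1[m1$clade == "A|B"]
  cd <- m1$prob1[m1$clade == "C|D"]
  expect_equal(ab, 1 - cd, tolerance = 1e-12)
})

test_that("the MCMC is seeded-reproducible with sane acceptance", {
  set.seed(21)
  tr <- ape::rtree(10)
  tr$edge.length <- tr$edge.length * 3
  trait <- binary_trait(setNames(
    as.character(simulate_binary_trait(tr, 0.3, 0.3, 7)$tip_states),
    tr$tip.label))
  b1 <- bbm_asr(tr, trait, generations = 1500, burnin = 300, thin = 5,
                seed = 9)
  b2 <- bbm_asr(tr, trait, generations = 1500, burnin = 300, thin = 5,
                seed = 9)
  expect_identical(attr(b1, "samples"), attr(b2, "samples"))
  expect_identical(b1$prob1, b2$prob1)
  expect_gt(attr(b1, "acceptance"), 0.05)
  expect_lt(attr(b1, "acceptance"), 0.9)
  expect_true(all(attr(b1, "ess") > 10))
})

test_that("a prior-only run returns the prior's stationary expectation", {
  tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  trait <- binary_trait(c(A = "?", B = "?", C = "?", D = "?"))
  b <- suppressWarnings(   # acceptance runs high: the likelihood is flat
    bbm_asr(tr, trait, generations = 4000, burnin = 500, thin = 5,
            seed = 3))
  ## symmetric iid priors on (q01, q10): E[pi_1] = 1/2
  expect_lt(max(abs(b$prob1 - 0.5)), 0.06)
})

test_that("origin counting recovers the published three-gain assignment", {
  f1 <- backbone_fixture("T1")
  tr <- f1$tree
  tr$edge.length <- rep(1, nrow(tr$edge))
  trait <- read_trait_tsv(system.file("extdata", "metallic_trait.tsv",
                                      package = "flyphy"))
  ## encode the published assignment: metallic clade a, metallic clade b,
  ## metallic Ameniinae, everything above them non-metallic
  asr <- marginal_asr(tr, trait, 0.1, 0.1)
  metallic_clades <- c("Chrysomyinae|Phumosiinae",
                       paste(sort(c("Rhiniidae", "Bengaliinae", "Luciliinae",
                                    "Calliphorinae", "Toxotarsinae")),
                             collapse = "|"),
                       "Bengaliinae|Rhiniidae",
                       paste(sort(c("Luciliinae", "Calliphorinae",
                                    "Toxotarsinae")), collapse = "|"),
                       "Calliphorinae|Toxotarsinae")
  asr$prob1 <- ifelse(asr$clade %in% metallic_clades, 0.95, 0.25)
  res <- count_origins(tr, trait, asr)
  expect_equal(res$n_gains, 3L)
  expect_equal(res$n_losses, 0L)

  ## degenerate cases
  asr1 <- asr
  asr1$prob1 <- rep(0.99, nrow(asr1))
  trait1 <- binary_trait(setNames(rep("1", 11), tr$tip.label))
  res1 <- count_origins(tr, trait1, asr1)
  expect_equal(res1$n_gains + res1$n_losses, 0L)
})

test_that("true change counts are bounded below by the Fitch score", {
  set.seed(31)
  tr <- ape::rtree(12)
  tr$edge.length <- tr$edge.length * 2
  for (s in 1:10) {
    sim <- simulate_binary_trait(tr, 0.4, 0.4, seed = s)
    aln <- flyphy:::.trait_aln(
      binary_trait(setNames(as.character(sim$tip_states),
                            names(sim$tip_states))), tr$tip.label)
    expect_gte(sum(sim$branch_changes), fitch_score(tr, aln))
  }
})
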