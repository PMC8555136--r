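# Ancestral-state reconstruction of a binary trait (adult metallic
# coloration): two-state Markov ML rates, exact marginal reconstruction by
# the up-down algorithm, a Bayesian sampler averaging the marginals over
# the rate posterior, and origin counting on the reconstructed states.

#' Binary trait vector
#'
#' @param x named vector of tip states coded `"0"` (absent), `"1"`
#'   (present) or `"?"` (unknown).
#' @return named character vector of class `binary_trait`.
#' @export
binary_trait <- function(x) {
  v <- as.character(unlist(x))
  names(v) <- names(x)
  .stop_if(is.null(names(v)) || anyDuplicated(names(v)) > 0L,
           "trait states must be uniquely named by taxon")
  bad <- setdiff(unique(v), c("0", "1", "?"))
  .stop_if(length(bad) > 0L, "trait states must be 0, 1 or ?; got: ",
           paste(bad, collapse = ", "))
  structure(v, class = "binary_trait")
}

#' @rdname binary_trait
#' @param file TSV with columns `taxon` and `state`.
#' @export
read_trait_tsv <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          colClasses = "character")
  binary_trait(stats::setNames(df$state, df$taxon))
}

## one-column alignment from a trait, over the given tips
.trait_aln <- function(trait, tips) {
  v <- unclass(trait)[tips]
  miss <- tips[is.na(v)]
  .stop_if(length(miss) > 0L, "no trait state for: ",
           paste(miss, collapse = ", "))
  m <- matrix(v, ncol = 1L)
  rownames(m) <- tips
  phy_alignment(m, alphabet_binary())
}

#' Fit the two-state Markov (Mk2) model
#'
#' Maximum-likelihood gain (`q01`) and loss (`q10`) rates by bounded 2-D
#' optimisation of the pruning likelihood, with the root at the stationary
#' frequencies of the rates.  Rates are bounded to `[1e-6, 1e3]`.
#'
#' @param tree rooted [ape::phylo] with branch lengths.
#' @param trait a [binary_trait()] covering the tips (`"?"` allowed).
#' @param equal_rates constrain `q01 = q10` (the "equal weight" character
#'   treatment)?
#' @return list with `q01`, `q10` and `lnL`.
#' @export
fit_mk2 <- function(tree, trait, equal_rates = FALSE) {
  aln <- .trait_aln(trait, tree$tip.label)
  obs <- unique(aln$seq[aln$seq %in% c("0", "1")])
  .stop_if(length(obs) < 2L,
           "trait is monomorphic among observed tips; rates are not ",
           "estimable (the ancestral state is trivially the observed one)")
  nll <- function(lq) {
    q <- exp(lq)
    if (equal_rates) q <- c(q[1L], q[1L])
    -tree_loglik(tree, aln, model_mk2(q[1L], q[2L]))$loglik
  }
  if (equal_rates) {
    opt <- stats::optimize(function(l) nll(l), log(c(1e-6, 1e3)))
    q <- rep(exp(opt$minimum), 2L)
    lnl <- -opt$objective
  } else {
    opt <- stats::optim(log(c(0.1, 0.1)), nll, method = "L-BFGS-B",
                        lower = log(1e-6), upper = log(1e3))
    q <- exp(opt$par)
    lnl <- -opt$value
  }
  list(q01 = q[1L], q10 = q[2L], lnL = lnl)
}

## up-down marginal probabilities for the 2-state model.
## Returns matrix (Nnode x 2) of P(state | data) per internal node.
.mk2_marginals <- function(tree, aln, q01, q10, root_prior) {
  model <- model_mk2(q01, q10)
  eig <- .model_eigen(model)
  pi <- switch(root_prior, stationary = model$freqs, flat = c(0.5, 0.5))
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  nn <- ntip + tr$Nnode
  sets <- .state_sets(alphabet_binary())
  char <- aln$seq[tr$tip.label, 1L]
  ## down pass in log-safe plain arithmetic (2 states, small trees)
  down <- matrix(1, nn, 2L)
  dscale <- numeric(nn)
  for (i in seq_len(ntip)) {
    down[i, ] <- 0
    down[i, sets[[char[i]]]] <- 1
  }
  P <- vector("list", nrow(tr$edge))
  for (r in seq_len(nrow(tr$edge))) {
    P[[r]] <- .pmat(eig, tr$edge.length[r])
    par <- tr$edge[r, 1L]
    ch <- tr$edge[r, 2L]
    down[par, ] <- down[par, ] * as.numeric(P[[r]] %*% down[ch, ])
    dscale[par] <- dscale[par] + dscale[ch]
  }
  ## renormalise progressively (postorder already done, rescale parents)
  ## (for small trees plain doubles suffice; rescale only if tiny)
  up <- matrix(0, nn, 2L)
  up[root, ] <- pi
  for (r in rev(seq_len(nrow(tr$edge)))) {
    par <- tr$edge[r, 1L]
    ch <- tr$edge[r, 2L]
    ## flank of child = (up[par] * product of siblings' lifted partials)
    ## lifted through the child's own edge
    sib <- down[par, ] / pmax(as.numeric(P[[r]] %*% down[ch, ]), 1e-300)
    up[ch, ] <- as.numeric(crossprod(P[[r]], up[par, ] * sib))
  }
  marg <- up * down
  marg <- marg / rowSums(marg)
  marg[(ntip + 1L):nn, , drop = FALSE]
}

## descendant-tip key for each internal node (stable node identity)
.node_keys <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  desc <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tr$tip.label[i]
  for (r in seq_len(nrow(tr$edge))) {
    par <- tr$edge[r, 1L]
    ch <- tr$edge[r, 2L]
    desc[[par]] <- c(desc[[par]], desc[[ch]])
  }
  vapply(desc[(ntip + 1L):(ntip + tr$Nnode)], function(d)
    paste(sort(d), collapse = "|"), character(1L))
}

#' Marginal ancestral-state reconstruction
#'
#' Exact per-node marginal probabilities of the derived state under the
#' Mk2 model with fixed rates, by the up-down (inside-outside) algorithm.
#' Tips coded `"?"` are fully ambiguous.
#'
#' @inheritParams fit_mk2
#' @param q01,q10 gain and loss rates, `> 0`.
#' @param root_prior `"stationary"` (default) or `"flat"`.
#' @return object of class `asr_result`: data frame with `node` (ape node
#'   id), `clade` (sorted descendant tips, `|`-joined), `prob1`; rates and
#'   method recorded as attributes.
#' @export
marginal_asr <- function(tree, trait, q01, q10,
                         root_prior = c("stationary", "flat")) {
  root_prior <- match.arg(root_prior)
  .stop_if(!(q01 > 0 && q10 > 0), "rates must be > 0")
  aln <- .trait_aln(trait, tree$tip.label)
  marg <- .mk2_marginals(tree, aln, q01, q10, root_prior)
  ntip <- length(tree$tip.label)
  structure(data.frame(node = ntip + seq_len(tree$Nnode),
                       clade = .node_keys(tree),
                       prob1 = marg[, 2L],
                       stringsAsFactors = FALSE),
            class = c("asr_result", "data.frame"),
            method = "ML marginal", q01 = q01, q10 = q10,
            root_prior = root_prior)
}

#' Bayesian binary MCMC ancestral-state reconstruction
#'
#' Metropolis-Hastings over `(q01, q10)` with independent exponential
#' priors and Gaussian proposals on the log scale; node probabilities are
#' the posterior mean of [marginal_asr()] over the retained samples.  A
#' trait of all-`"?"` tips gives a prior-predictive run (constant
#' likelihood).
#'
#' @inheritParams marginal_asr
#' @param prior_mean mean of the exponential rate priors.
#' @param proposal_sd standard deviation of the log-scale random walk.
#' @param generations total MCMC iterations.
#' @param burnin discarded initial iterations (must be < `generations`).
#' @param thin keep every `thin`-th sample after burn-in.
#' @param seed integer seed.
#' @return an `asr_result` data frame (posterior-mean `prob1`), with the
#'   posterior rate samples in `attr(, "samples")`, the acceptance rate in
#'   `attr(, "acceptance")` and effective sample sizes in `attr(, "ess")`.
#' @export
bbm_asr <- function(tree, trait, prior_mean = 1, proposal_sd = 0.3,
                    generations = 10000L, burnin = 2000L, thin = 10L,
                    seed = 1L, root_prior = c("stationary", "flat")) {
  root_prior <- match.arg(root_prior)
  .stop_if(generations <= burnin, "generations must exceed burnin")
  aln <- .trait_aln(trait, tree$tip.label)
  all_unknown <- all(aln$seq == "?")
  set.seed(seed)
  loglik <- function(q) {
    if (all_unknown) return(0)
    tree_loglik(tree, aln, model_mk2(q[1L], q[2L]))$loglik
  }
  logpost <- function(lq) {
    q <- exp(lq)
    ## exponential prior on the natural scale + log-scale Jacobian
    loglik(q) + sum(stats::dexp(q, 1 / prior_mean, log = TRUE)) + sum(lq)
  }
  lq <- log(c(0.1, 0.1))
  lp <- logpost(lq)
  keep_iters <- seq(burnin + thin, generations, by = thin)
  samples <- matrix(0, length(keep_iters), 2L,
                    dimnames = list(NULL, c("q01", "q10")))
  prob_acc <- NULL
  accepted <- 0L
  kidx <- 0L
  for (it in seq_len(generations)) {
    prop <- lq + stats::rnorm(2L, 0, proposal_sd)
    lp_prop <- logpost(prop)
    if (log(stats::runif(1L)) < lp_prop - lp) {
      lq <- prop
      lp <- lp_prop
      accepted <- accepted + 1L
    }
    if (it %in% keep_iters) {
      kidx <- kidx + 1L
      q <- exp(lq)
      samples[kidx, ] <- q
      marg <- .mk2_marginals(tree, aln, q[1L], q[2L], root_prior)[, 2L]
      prob_acc <- if (is.null(prob_acc)) marg else prob_acc + marg
    }
  }
  acc_rate <- accepted / generations
  if (acc_rate < 0.05 || acc_rate > 0.8)
    warning("MCMC acceptance rate ", signif(acc_rate, 3),
            " outside [0.05, 0.8]; consider tuning proposal_sd",
            call. = FALSE)
  prob1 <- prob_acc / length(keep_iters)
  ntip <- length(tree$tip.label)
  structure(data.frame(node = ntip + seq_len(tree$Nnode),
                       clade = .node_keys(tree),
                       prob1 = prob1,
                       stringsAsFactors = FALSE),
            class = c("asr_result", "data.frame"),
            method = "Bayesian posterior mean",
            samples = samples, acceptance = acc_rate,
            ess = apply(samples, 2L, .ess),
            q01 = mean(samples[, 1L]), q10 = mean(samples[, 2L]),
            root_prior = root_prior, seed = seed)
}

## effective sample size by truncated autocorrelation sum
.ess <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1L]
  neg <- which(ac < 0)
  if (length(neg) > 0L) ac <- ac[seq_len(neg[1L] - 1L)]
  n / (1 + 2 * sum(ac))
}

#' Count origins and losses of the derived state
#'
#' Assigns each node its higher-probability state (at `threshold = 0.5`
#' this is the argmax; ties take the parent's state, a root tie takes
#' state 0), tips keep their observed states (`"?"` tips inherit the
#' parent's assignment), and transitions are counted along edges: a gain
#' is a 0-to-1 edge, a loss 1-to-0.
#'
#' @param tree the tree the reconstruction was computed on.
#' @param trait the [binary_trait()] of tip states.
#' @param asr an `asr_result` from [marginal_asr()] or [bbm_asr()].
#' @param threshold probability needed to assign state 1, in `[0.5, 1]`
#'   (0.5 means strict argmax).
#' @return list with `n_gains`, `n_losses`, and `states` (assignment by
#'   node id, tips first).
#' @export
count_origins <- function(tree, trait, asr, threshold = 0.5) {
  stopifnot(inherits(asr, "asr_result"))
  .stop_if(!(threshold >= 0.5 && threshold <= 1),
           "threshold must be in [0.5, 1]")
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nn <- ntip + tr$Nnode
  v <- unclass(trait)[tr$tip.label]
  prob1 <- stats::setNames(asr$prob1, asr$node)
  state <- rep(NA_integer_, nn)
  state[seq_len(ntip)] <- ifelse(v == "1", 1L, ifelse(v == "0", 0L, NA))
  assign_node <- function(nd, parent_state) {
    p <- prob1[[as.character(nd)]]
    if (p > threshold || (threshold == 0.5 && p > 0.5)) 1L
    else if (p < 1 - threshold || (threshold == 0.5 && p < 0.5)) 0L
    else if (is.null(parent_state) || is.na(parent_state)) 0L  # root tie
    else parent_state
  }
  root <- ntip + 1L
  state[root] <- assign_node(root, NULL)
  for (r in rev(seq_len(nrow(tr$edge)))) {  # preorder
    par <- tr$edge[r, 1L]
    ch <- tr$edge[r, 2L]
    if (ch > ntip) {
      state[ch] <- assign_node(ch, state[par])
    } else if (is.na(state[ch])) {
      state[ch] <- state[par]  # unknown tip: no change counted
    }
  }
  gains <- 0L
  losses <- 0L
  for (r in seq_len(nrow(tr$edge))) {
    s1 <- state[tr$edge[r, 1L]]
    s2 <- state[tr$edge[r, 2L]]
    if (s1 == 0L && s2 == 1L) gains <- gains + 1L
    if (s1 == 1L && s2 == 0L) losses <- losses + 1L
  }
  list(n_gains = gains, n_losses = losses, states = state)
}

#' Write per-node ancestral probabilities as TSV
#'
#' Nodes are keyed by their sorted descendant tip sets.
#'
#' @param asr an `asr_result`.
#' @param file output path.
#' @export
write_asr_tsv <- function(asr, file) {
  stopifnot(inherits(asr, "asr_result"))
  .write_tsv(as.data.frame(asr), file)
}
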