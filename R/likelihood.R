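# Felsenstein pruning over discrete-gamma rate classes.
#
# The engine works on compressed site patterns.  Partial likelihoods are
# rescaled at every internal node (per pattern, per rate class) with the
# rescaling factors accumulated in log space, so supermatrices far beyond
# 1e5 sites stay in range.  For a reversible model P(t) factorises through
# the symmetric eigendecomposition (see .model_eigen), which both gives the
# matrix exponential and lets a single branch's likelihood be re-evaluated
# in O(states x patterns) during branch-length optimisation.

## Collapse duplicate columns; returns pattern matrix, weights, site->pattern.
.pattern_compress <- function(mat) {
  keys <- do.call(paste0, lapply(seq_len(nrow(mat)), function(i) mat[i, ]))
  f <- factor(keys, levels = unique(keys))
  map <- as.integer(f)
  first <- which(!duplicated(map))
  list(mat = mat[, first, drop = FALSE],
       w = as.numeric(tabulate(map, nbins = length(first))),
       map = map)
}

## Model-independent data preparation: tree traversal order, site patterns,
## per-tip symbol codings.
.prep_data <- function(tree, aln, alphabet) {
  validate_tree(tree)
  stopifnot(inherits(aln, "phy_alignment"))
  .stop_if(!identical(alphabet$name, aln$alphabet$name),
           "alignment alphabet (", aln$alphabet$name,
           ") does not match the model alphabet (", alphabet$name, ")")
  missing <- setdiff(tree$tip.label, aln_taxa(aln))
  .stop_if(length(missing) > 0L, "taxa in tree but not in alignment: ",
           paste(missing, collapse = ", "))
  tr <- ape::reorder.phylo(tree, "postorder")
  mat <- aln$seq[tr$tip.label, , drop = FALSE]
  pat <- .pattern_compress(mat)
  nstates <- length(alphabet$states)
  sets <- .state_sets(alphabet)
  ntip <- length(tr$tip.label)
  tipT <- vector("list", ntip)
  tipidx <- vector("list", ntip)
  for (i in seq_len(ntip)) {
    chars <- pat$mat[i, ]
    u <- unique(chars)
    Tm <- matrix(0, nstates, length(u))
    for (j in seq_along(u)) Tm[sets[[u[j]]], j] <- 1
    tipT[[i]] <- Tm
    tipidx[[i]] <- match(chars, u)
  }
  kids <- vector("list", ntip + tr$Nnode)
  for (r in seq_len(nrow(tr$edge))) {
    p <- tr$edge[r, 1L]
    kids[[p]] <- c(kids[[p]], r)
  }
  list(tree = tr, ntip = ntip, root = ntip + 1L, edge = tr$edge,
       elen = tr$edge.length, kids = kids, nstates = nstates,
       tipT = tipT, tipidx = tipidx,
       w = pat$w, map = pat$map, npat = length(pat$w))
}

.model_terms <- function(model) {
  rc <- .rate_classes(model)
  c(list(eig = .model_eigen(model), pi = model$freqs), rc)
}

## One postorder pass.  Returns total log-likelihood, per-pattern
## log-likelihoods, and (optionally) all internal partials and their
## log-scalers for use by the branch optimiser.
.down_pass <- function(pp, mt, elen, keep = FALSE) {
  ncat <- length(mt$rates)
  nn <- pp$ntip + pp$tree$Nnode
  down <- vector("list", nn)
  slog <- vector("list", nn)
  contrib <- function(child, t, cat) {
    P <- .pmat(mt$eig, t * mt$rates[cat])
    if (child <= pp$ntip) {
      PT <- P %*% pp$tipT[[child]]
      PT[, pp$tipidx[[child]], drop = FALSE]
    } else P %*% down[[child]][[cat]]
  }
  parents <- unique(pp$edge[, 1L])  # postorder: children before parents
  for (nd in parents) {
    rows <- pp$kids[[nd]]
    dn <- vector("list", ncat)
    sl <- vector("list", ncat)
    for (cat in seq_len(ncat)) {
      X <- NULL
      sacc <- 0
      for (r in rows) {
        ch <- pp$edge[r, 2L]
        cc <- contrib(ch, elen[r], cat)
        X <- if (is.null(X)) cc else X * cc
        if (ch > pp$ntip) sacc <- sacc + slog[[ch]][[cat]]
      }
      s <- .colmax(X)
      .stop_if(any(s <= 0 | !is.finite(s)),
               "non-finite partial likelihood at node ", nd)
      X <- X * rep(1 / s, each = pp$nstates)
      dn[[cat]] <- X
      sl[[cat]] <- sacc + log(s)
    }
    down[[nd]] <- dn
    slog[[nd]] <- sl
  }
  logs <- matrix(0, ncat, pp$npat)
  for (cat in seq_len(ncat)) {
    sitel <- crossprod(mt$pi, down[[pp$root]][[cat]])[1L, ]
    sitel[sitel < 1e-300] <- 1e-300
    logs[cat, ] <- log(mt$weights[cat]) + log(sitel) + slog[[pp$root]][[cat]]
  }
  pat_ll <- .logsumexp_rows(logs)
  out <- list(loglik = sum(pp$w * pat_ll), pat_ll = pat_ll)
  if (keep) {
    out$down <- down
    out$slog <- slog
  }
  out
}

#' Tree log-likelihood
#'
#' Felsenstein pruning over the model's discrete rate classes; ambiguity
#' symbols contribute a partial likelihood of 1 for every compatible state.
#' The per-site vector sums to the total (log-scale compensated through
#' per-node rescaling).
#'
#' @param tree an [ape::phylo] tree with branch lengths; its tips must be a
#'   subset of the alignment's taxa.
#' @param aln a [phy_alignment()].
#' @param model a [substitution_model()].
#' @return list with `loglik` (scalar) and `site_loglik` (numeric vector,
#'   one entry per alignment column).
#' @export
tree_loglik <- function(tree, aln, model) {
  .stop_if(is.null(tree$edge.length), "tree must have branch lengths")
  pp <- .prep_data(tree, aln, model$alphabet)
  dp <- .down_pass(pp, .model_terms(model), pp$elen)
  list(loglik = dp$loglik, site_loglik = dp$pat_ll[pp$map])
}

## log-likelihood of a single branch as a function of its length, given the
## flank partial G (with log-scalers gs) and the subtree partial term
## Z[[cat]] = (C1' G) * (C2 L).
.edge_loglik_fun <- function(pp, mt, Z, sl) {
  ncat <- length(mt$rates)
  function(t) {
    logs <- matrix(0, ncat, pp$npat)
    for (cat in seq_len(ncat)) {
      fv <- crossprod(exp(mt$eig$lambda * (t * mt$rates[cat])), Z[[cat]])[1L, ]
      fv[fv < 1e-300] <- 1e-300
      logs[cat, ] <- log(mt$weights[cat]) + log(fv) + sl[[cat]]
    }
    sum(pp$w * .logsumexp_rows(logs))
  }
}

## One preorder sweep of per-branch Brent updates.  `dp` holds the current
## postorder partials; flank ("up") partials are built on the way down and
## refreshed with each newly optimised branch.
.edge_cycle <- function(pp, mt, elen, dp, tol, max_bl) {
  ncat <- length(mt$rates)
  ns <- pp$nstates
  A <- vector("list", pp$ntip + pp$tree$Nnode)
  As <- vector("list", length(A))
  A[[pp$root]] <- rep(list(matrix(mt$pi, ns, pp$npat)), ncat)
  As[[pp$root]] <- rep(list(numeric(pp$npat)), ncat)
  stack <- pp$root
  while (length(stack) > 0L) {
    u <- stack[length(stack)]
    stack <- stack[-length(stack)]
    rows <- pp$kids[[u]]
    children <- pp$edge[rows, 2L]
    contrib <- vector("list", length(rows))
    cslog <- vector("list", length(rows))
    mk_contrib <- function(k) {
      v <- children[k]
      t <- elen[rows[k]]
      cc <- vector("list", ncat)
      cs <- vector("list", ncat)
      for (cat in seq_len(ncat)) {
        P <- .pmat(mt$eig, t * mt$rates[cat])
        if (v <= pp$ntip) {
          PT <- P %*% pp$tipT[[v]]
          cc[[cat]] <- PT[, pp$tipidx[[v]], drop = FALSE]
          cs[[cat]] <- numeric(pp$npat)
        } else {
          cc[[cat]] <- P %*% dp$down[[v]][[cat]]
          cs[[cat]] <- dp$slog[[v]][[cat]]
        }
      }
      list(cc = cc, cs = cs)
    }
    for (k in seq_along(rows)) {
      tmp <- mk_contrib(k)
      contrib[[k]] <- tmp$cc
      cslog[[k]] <- tmp$cs
    }
    for (k in seq_along(rows)) {
      v <- children[k]
      r <- rows[k]
      G <- vector("list", ncat)
      Gs <- vector("list", ncat)
      for (cat in seq_len(ncat)) {
        X <- A[[u]][[cat]]
        sacc <- As[[u]][[cat]]
        for (j in seq_along(rows)) if (j != k) {
          X <- X * contrib[[j]][[cat]]
          sacc <- sacc + cslog[[j]][[cat]]
        }
        G[[cat]] <- X
        Gs[[cat]] <- sacc
      }
      Z <- vector("list", ncat)
      sl <- vector("list", ncat)
      for (cat in seq_len(ncat)) {
        L <- if (v <= pp$ntip) {
          C2T <- mt$eig$C2 %*% pp$tipT[[v]]
          C2T[, pp$tipidx[[v]], drop = FALSE]
        } else mt$eig$C2 %*% dp$down[[v]][[cat]]
        Z[[cat]] <- crossprod(mt$eig$C1, G[[cat]]) * L
        sl[[cat]] <- Gs[[cat]] +
          (if (v <= pp$ntip) 0 else dp$slog[[v]][[cat]])
      }
      f <- .edge_loglik_fun(pp, mt, Z, sl)
      t_cur <- elen[r]
      upper <- max(0.5, 4 * t_cur)
      repeat {
        opt <- stats::optimize(function(t) -f(t), c(0, upper), tol = tol)
        if (opt$minimum < 0.95 * upper || upper >= max_bl) break
        upper <- min(2 * upper, max_bl)
      }
      .stop_if(!is.finite(opt$objective),
               "non-finite likelihood while optimising branch ", r)
      cand <- c(t_cur, opt$minimum, 0)
      vals <- c(f(t_cur), -opt$objective, f(0))
      elen[r] <- cand[which.max(vals)]
      if (elen[r] != t_cur) {
        tmp <- mk_contrib(k)
        contrib[[k]] <- tmp$cc
        cslog[[k]] <- tmp$cs
      }
      if (v > pp$ntip) {
        Av <- vector("list", ncat)
        Avs <- vector("list", ncat)
        for (cat in seq_len(ncat)) {
          P <- .pmat(mt$eig, elen[r] * mt$rates[cat])
          X <- crossprod(P, G[[cat]])
          s <- .colmax(X)
          s[s <= 0] <- 1e-300
          Av[[cat]] <- X * rep(1 / s, each = ns)
          Avs[[cat]] <- Gs[[cat]] + log(s)
        }
        A[[v]] <- Av
        As[[v]] <- Avs
        stack <- c(stack, v)
      }
    }
    A[u] <- list(NULL)   # free memory without shifting list indices
    As[u] <- list(NULL)
  }
  elen
}

#' Optimise branch lengths on a fixed topology
#'
#' Cyclic single-branch optimisation: each sweep recomputes the postorder
#' partials, then walks the tree in preorder applying Brent's method to one
#' branch at a time with the flanking partials held fixed.  Iteration stops
#' when a full sweep improves the log-likelihood by less than `tol` or after
#' `max_cycles` sweeps; the returned tree never has a lower log-likelihood
#' than the input.
#'
#' @inheritParams tree_loglik
#' @param tol convergence tolerance (log-likelihood units, and the Brent
#'   x-tolerance per branch).
#' @param max_cycles maximum number of full sweeps.
#' @param max_bl upper bound for a single branch length.
#' @return the tree with optimised `edge.length` and the final
#'   log-likelihood in `attr(, "loglik")`.
#' @export
optimize_branch_lengths <- function(tree, aln, model, tol = 1e-6,
                                    max_cycles = 20L, max_bl = 10) {
  .stop_if(is.null(tree$edge.length), "tree must have branch lengths")
  pp <- .prep_data(tree, aln, model$alphabet)
  mt <- .model_terms(model)
  elen <- pp$elen
  best_ll <- -Inf
  best_elen <- elen
  prev <- -Inf
  for (cycle in seq_len(max_cycles)) {
    dp <- .down_pass(pp, mt, elen, keep = TRUE)
    .stop_if(!is.finite(dp$loglik), "non-finite likelihood during search")
    if (dp$loglik > best_ll) {
      best_ll <- dp$loglik
      best_elen <- elen
    }
    if (cycle > 1L && dp$loglik - prev < tol) break
    prev <- dp$loglik
    elen <- .edge_cycle(pp, mt, elen, dp, tol, max_bl)
  }
  dp <- .down_pass(pp, mt, elen)
  if (dp$loglik > best_ll) {
    best_ll <- dp$loglik
    best_elen <- elen
  }
  out <- pp$tree
  out$edge.length <- best_elen
  attr(out, "loglik") <- best_ll
  out
}

#' Optimise free model parameters
#'
#' Coordinate-wise maximum-likelihood fitting of the parameters named in
#' `free`: `"alpha"` (gamma shape, bounded to `[0.02, 100]`),
#' `"freqs"` (equilibrium frequencies via a softmax parameterisation), and
#' `"binary_rates"` (the two trait rates, bounded to `[1e-6, 1e3]`).
#' The likelihood never decreases; branch lengths are held fixed.
#'
#' @inheritParams tree_loglik
#' @param free character subset of
#'   `c("alpha", "freqs", "binary_rates")`; empty means return the model
#'   unchanged.
#' @return the updated [substitution_model()] with the final log-likelihood
#'   in `attr(, "loglik")`.
#' @export
optimize_model_parameters <- function(tree, aln, model, free = character()) {
  .stop_if(aln_nsites(aln) == 0L, "empty alignment")
  allowed <- c("alpha", "freqs", "binary_rates")
  bad <- setdiff(free, allowed)
  .stop_if(length(bad) > 0L, "unknown parameter(s): ",
           paste(bad, collapse = ", "))
  if (length(free) == 0L) return(model)
  pp <- .prep_data(tree, aln, model$alphabet)
  ll_of <- function(m) .down_pass(pp, .model_terms(m), pp$elen)$loglik
  rounds <- if (length(free) > 1L) 2L else 1L
  for (round in seq_len(rounds)) {
    if ("alpha" %in% free) {
      .stop_if(is.null(model$alpha),
               "model has no gamma component; set alpha before freeing it")
      opt <- stats::optimize(function(la) {
        m <- model
        m$alpha <- exp(la)
        ll_of(m)
      }, log(c(0.02, 100)), maximum = TRUE, tol = 1e-4)
      model$alpha <- exp(opt$maximum)
    }
    if ("freqs" %in% free) {
      n <- length(model$freqs)
      par0 <- log(model$freqs)[-n] - log(model$freqs)[n]
      opt <- stats::optim(par0, function(p) {
        w <- exp(c(p, 0))
        m <- model
        m$freqs <- w / sum(w)
        -ll_of(m)
      }, method = "Nelder-Mead", control = list(maxit = 500))
      w <- exp(c(opt$par, 0))
      model$freqs <- w / sum(w)
    }
    if ("binary_rates" %in% free) {
      .stop_if(model$alphabet$name != "binary",
               "binary_rates only applies to two-state trait models")
      q0 <- .mk2_rates(model)
      opt <- stats::optim(log(q0), function(lq) {
        q <- exp(lq)
        -ll_of(model_mk2(q[1L], q[2L]))
      }, method = "L-BFGS-B", lower = log(1e-6), upper = log(1e3))
      q <- exp(opt$par)
      model <- model_mk2(q[1L], q[2L])
    }
  }
  attr(model, "loglik") <- ll_of(model)
  model
}

## recover (q01, q10) from a binary phy_model
.mk2_rates <- function(model) {
  Q <- build_rate_matrix(model)
  c(q01 = Q[1L, 2L], q10 = Q[2L, 1L])
}
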