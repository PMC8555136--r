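# Per-partition log-likelihood comparison and RELL-based topology tests.
#
# The central quantity is the per-site log-likelihood matrix (trees x
# sites).  Per-gene likelihoods are sums of site terms inside the gene's
# partition, so the per-gene table is exactly additive: summing a gene
# column reproduces each tree's total.  KH/SH/AU all resample the stored
# site terms (RELL) instead of re-optimising anything.

#' Per-partition log-likelihood differences
#'
#' Scores every gene against each hypothesis tree and tabulates
#' \eqn{\Delta pL_i} for the first tree against each of the others (for the
#' canonical T1/T2/T3 comparison: `T1 - T2` and `T1 - T3`).  Branch lengths
#' are, by default, optimised once per tree on the full supermatrix and then
#' held fixed for per-gene scoring; set `optimize_branches = FALSE` if the
#' supplied trees already carry their maximum-likelihood lengths.
#'
#' @param aln a [phy_alignment()].
#' @param parts a [partition_map()] covering the alignment.
#' @param trees named list of hypothesis trees (2 or more; first is the
#'   reference of every comparison).
#' @param model a [substitution_model()].
#' @param optimize_branches optimise branch lengths on the full matrix
#'   before scoring?
#' @return object of class `delta_pl_table`: a data frame with one row per
#'   gene, per-tree log-likelihood columns `pL_<tree>`, and difference
#'   columns `delta_<first>_<other>`; total log-likelihoods, the per-site
#'   matrix and the (possibly re-optimised) trees are kept as attributes.
#' @export
per_partition_delta_pl <- function(aln, parts, trees, model,
                                   optimize_branches = TRUE) {
  .check_partitions(parts, aln_nsites(aln))
  .stop_if(any(parts$end - parts$start < 1L), "empty partition")
  .stop_if(length(trees) < 2L || is.null(names(trees)),
           "need a named list of at least two trees")
  site_ll <- matrix(0, length(trees), aln_nsites(aln),
                    dimnames = list(names(trees), NULL))
  fitted <- trees
  for (k in seq_along(trees)) {
    tr <- trees[[k]]
    if (optimize_branches) tr <- optimize_branch_lengths(tr, aln, model)
    fitted[[k]] <- tr
    site_ll[k, ] <- tree_loglik(tr, aln, model)$site_loglik
  }
  ngene <- nrow(parts)
  pl <- matrix(0, ngene, length(trees),
               dimnames = list(parts$gene, names(trees)))
  for (i in seq_len(ngene)) {
    cols <- (parts$start[i] + 1L):parts$end[i]
    pl[i, ] <- rowSums(site_ll[, cols, drop = FALSE])
  }
  out <- data.frame(gene = parts$gene, pl, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out)[-1L] <- paste0("pL_", names(trees))
  ref <- names(trees)[1L]
  for (other in names(trees)[-1L])
    out[[paste0("delta_", ref, "_", other)]] <-
      pl[, ref] - pl[, other]
  structure(out,
            class = c("delta_pl_table", "data.frame"),
            totals = rowSums(site_ll), site_ll = site_ll, trees = fitted,
            reference = ref)
}

#' Count genes favoring each side of a comparison
#'
#' Sign-based tally of a `delta_` column: positive favors the first tree of
#' the pair, negative the second.  Differences that vanish after rounding at
#' 1e-9 are reported as ties, never allocated to either side.
#'
#' @param table a [per_partition_delta_pl()] result.
#' @param pair character pair of tree names, e.g. `c("T1", "T2")`; the first
#'   must be the table's reference tree.
#' @return named integer vector `c(n_favor_first, n_favor_second, n_ties)`.
#' @export
count_favoring <- function(table, pair) {
  stopifnot(inherits(table, "delta_pl_table"))
  .stop_if(length(pair) != 2L, "pair must name two trees")
  col <- paste0("delta_", pair[1L], "_", pair[2L])
  .stop_if(!col %in% names(table), "comparison ", col,
           " not present in table")
  d <- table[[col]]
  d[abs(d) < 1e-9] <- 0
  c(n_favor_first = sum(d > 0), n_favor_second = sum(d < 0),
    n_ties = sum(d == 0))
}

#' RELL resampling of per-site log-likelihoods
#'
#' Each replicate draws `round(scale * n_sites)` sites with replacement and
#' sums the stored per-site log-likelihoods per tree; nothing is
#' re-optimised.  Implemented by multinomial weight vectors so a replicate
#' is a single matrix product.
#'
#' @param site_ll matrix (trees x sites) of per-site log-likelihoods.
#' @param scale positive resampling scale factor.
#' @param replicates number of bootstrap replicates.
#' @param seed integer seed.
#' @return matrix (trees x replicates) of replicate total log-likelihoods.
#' @export
rell_resample <- function(site_ll, scale = 1, replicates, seed) {
  .stop_if(!is.matrix(site_ll) || ncol(site_ll) == 0L || nrow(site_ll) == 0L,
           "empty site log-likelihood matrix")
  .stop_if(!(scale > 0), "scale must be > 0")
  .stop_if(!.is_count(replicates), "replicates must be >= 1")
  set.seed(seed)
  n <- ncol(site_ll)
  m <- max(1L, round(scale * n))
  counts <- stats::rmultinom(replicates, m, rep(1 / n, n))
  out <- site_ll %*% counts
  rownames(out) <- rownames(site_ll)
  out
}

## Bootstrap proportions at one scale; ties share a replicate equally.
.rell_bp <- function(reps) {
  ntree <- nrow(reps)
  mx <- apply(reps, 2L, max)
  is_max <- reps == rep(mx, each = ntree)
  share <- 1 / colSums(is_max)
  as.numeric(is_max %*% share) / ncol(reps)
}

#' KH, SH and AU topology tests
#'
#' RELL-based tree comparison on a fixed per-site log-likelihood matrix.
#' KH is the one-sided Kishino-Hasegawa test of each tree against the
#' maximum-likelihood tree with a mean-centred RELL null; SH is the
#' Shimodaira-Hasegawa test with the joint centred-max null; AU is the
#' approximately unbiased test: bootstrap proportions across resampling
#' scales are probit-transformed and fitted by weighted least squares to
#' \eqn{d\sqrt r + c/\sqrt r}, giving \eqn{p = 1 - \Phi(d - c)}.
#' Proportions are clamped to `[1/(2B), 1 - 1/(2B)]` before the transform;
#' a tree that is never best at any scale is reported with `p_AU = 1/(2B)`
#' and flagged.
#'
#' @param site_ll matrix (trees x sites), rownames = tree ids.
#' @param replicates bootstrap replicates per scale (B).
#' @param scales resampling scale factors.
#' @param seed integer seed.
#' @return object of class `topology_test_report`: data frame with columns
#'   `tree`, `logL`, `delta`, `p_KH`, `p_SH`, `p_AU`, `au_d`, `au_c`,
#'   `au_rss`, `flag`.
#' @export
topology_test_suite <- function(site_ll, replicates = 1000L,
                                scales = seq(0.5, 1.4, by = 0.1), seed = 1L) {
  .stop_if(!is.matrix(site_ll) || nrow(site_ll) < 2L,
           "need per-site log-likelihoods for at least 2 trees")
  ntree <- nrow(site_ll)
  ids <- rownames(site_ll) %||% paste0("tree", seq_len(ntree))
  totals <- rowSums(site_ll)
  best <- which.max(totals)
  delta <- totals[best] - totals
  B <- as.integer(replicates)

  ## scale-1 replicates drive KH and SH
  r1 <- rell_resample(site_ll, 1, B, .derive_seed(seed, 0L))
  cent <- r1 - rowMeans(r1)
  p_kh <- p_sh <- numeric(ntree)
  smax <- apply(cent, 2L, max)
  for (k in seq_len(ntree)) {
    if (k == best) {
      p_kh[k] <- 1
    } else {
      d0 <- cent[best, ] - cent[k, ]
      p_kh[k] <- mean(d0 - mean(d0) >= delta[k])
    }
    p_sh[k] <- mean(smax - cent[k, ] >= delta[k])
  }

  ## multiscale bootstrap proportions for AU
  bp <- matrix(0, ntree, length(scales))
  for (j in seq_along(scales)) {
    reps <- rell_resample(site_ll, scales[j], B, .derive_seed(seed, j))
    bp[, j] <- .rell_bp(reps)
  }
  lo <- 1 / (2 * B)
  bp_cl <- pmin(pmax(bp, lo), 1 - lo)
  p_au <- au_d <- au_c <- au_rss <- numeric(ntree)
  flag <- character(ntree)
  x <- cbind(sqrt(scales), 1 / sqrt(scales))
  for (k in seq_len(ntree)) {
    if (all(bp[k, ] <= 0)) {
      p_au[k] <- lo
      au_d[k] <- NA_real_
      au_c[k] <- NA_real_
      au_rss[k] <- NA_real_
      flag[k] <- "never_best"
      next
    }
    z <- stats::qnorm(1 - bp_cl[k, ])
    w <- B * stats::dnorm(z)^2 / (bp_cl[k, ] * (1 - bp_cl[k, ]))
    fit <- stats::lm.wfit(x, z, w)
    au_d[k] <- fit$coefficients[1L]
    au_c[k] <- fit$coefficients[2L]
    au_rss[k] <- sum(w * fit$residuals^2)
    p_au[k] <- 1 - stats::pnorm(au_d[k] - au_c[k])
    if (all(bp[k, ] >= 1)) flag[k] <- "always_best"
    if (k != best && delta[k] == 0) flag[k] <- "tie_with_best"
    if (max(bp[k, ]) <= lo) {
      p_au[k] <- lo
      flag[k] <- "never_best"
    }
  }
  structure(data.frame(tree = ids, logL = totals, delta = delta,
                       p_KH = p_kh, p_SH = p_sh, p_AU = p_au,
                       au_d = au_d, au_c = au_c, au_rss = au_rss,
                       flag = flag, row.names = NULL,
                       stringsAsFactors = FALSE),
            class = c("topology_test_report", "data.frame"),
            replicates = B, scales = scales, seed = seed)
}
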