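#' Reversible substitution models
#'
#' A continuous-time Markov model over an alphabet, parameterised GTR-style by
#' symmetric exchangeabilities and equilibrium frequencies, with optional
#' discrete-gamma rate heterogeneity and a proportion of invariant sites.
#' The generator is \eqn{Q_{ij} = s_{ij}\pi_j} (off-diagonal) with the diagonal
#' set so rows sum to zero; by default it is rescaled so the expected number of
#' substitutions per unit branch length is 1 at stationarity.  Trait models
#' (e.g. the two-state gain/loss model) switch that rescaling off because
#' their rates are meaningful in absolute time units of the tree.
#'
#' @param alphabet a [phy_alphabet()].
#' @param exch symmetric matrix of exchangeability coefficients (diagonal
#'   ignored), or a single number for equal exchangeabilities.
#' @param freqs equilibrium frequencies, positive, summing to 1.
#' @param alpha gamma shape for among-site rate variation, or `NULL` for none.
#' @param ncat number of discrete gamma categories (ignored when
#'   `alpha = NULL`).
#' @param pinv proportion of invariant sites in `[0, 1)`.
#' @param normalize rescale `Q` to one expected substitution per unit length?
#' @param name optional model label.
#' @return An object of class `phy_model`.
#' @export
substitution_model <- function(alphabet, exch, freqs, alpha = NULL,
                               ncat = 4L, pinv = 0, normalize = TRUE,
                               name = "custom") {
  stopifnot(inherits(alphabet, "phy_alphabet"))
  n <- length(alphabet$states)
  if (length(exch) == 1L) exch <- matrix(exch, n, n)
  exch <- as.matrix(exch)
  .stop_if(!all(dim(exch) == n), "exchangeability matrix has wrong dimension")
  .stop_if(max(abs(exch - t(exch))) > 1e-12, "exchangeabilities must be symmetric")
  diag(exch) <- 0
  .stop_if(any(exch < 0) || all(exch == 0),
           "exchangeabilities must be >= 0 with at least one > 0")
  .stop_if(length(freqs) != n, "frequency vector has wrong length")
  .stop_if(any(freqs <= 0), "zero or negative equilibrium frequency: ",
           "reversibility is undefined")
  freqs <- freqs / sum(freqs)
  if (!is.null(alpha)) {
    .stop_if(!(is.numeric(alpha) && alpha > 0), "gamma shape must be > 0")
    .stop_if(!.is_count(ncat), "ncat must be a positive integer")
  } else ncat <- 1L
  .stop_if(pinv < 0 || pinv >= 1, "pinv must lie in [0, 1)")
  structure(list(alphabet = alphabet, exch = exch, freqs = freqs,
                 alpha = alpha, ncat = as.integer(ncat), pinv = pinv,
                 normalize = isTRUE(normalize), name = name),
            class = "phy_model")
}

#' @export
print.phy_model <- function(x, ...) {
  cat("<phy_model>", x$name, "on", x$alphabet$name, "alphabet")
  if (!is.null(x$alpha)) cat(sprintf(" +G%d(alpha=%.4g)", x$ncat, x$alpha))
  if (x$pinv > 0) cat(sprintf(" +I(%.3g)", x$pinv))
  cat("\n")
  invisible(x)
}

#' Ready-made models
#'
#' `model_jc()` is Jukes-Cantor (equal rates/frequencies, nucleotides);
#' `model_gtr()` takes the six lower-triangle exchangeabilities in
#' AC, AG, AT, CG, CT, GT order; `model_poisson()` is the equal-rates,
#' equal-frequency amino-acid model; `model_lg()` uses the empirical LG
#' exchangeabilities and frequencies (as distributed with phangorn);
#' `model_dayhoff6()` is the equal-exchangeability six-state model for
#' Dayhoff-recoded matrices; `model_mk2()` is the two-state trait model with
#' gain rate `q01` and loss rate `q10` (unnormalised: branch lengths keep
#' their time units).
#'
#' @param alpha,ncat,pinv rate-heterogeneity settings, see
#'   [substitution_model()].
#' @param rates six GTR exchangeabilities.
#' @param freqs equilibrium frequencies.
#' @param q01,q10 gain (0 to 1) and loss (1 to 0) rates, both > 0.
#' @name model_presets
NULL

#' @rdname model_presets
#' @export
model_jc <- function(alpha = NULL, ncat = 4L, pinv = 0)
  substitution_model(alphabet_nt(), 1, rep(0.25, 4), alpha, ncat, pinv,
                     name = "JC")

#' @rdname model_presets
#' @export
model_gtr <- function(rates, freqs, alpha = NULL, ncat = 4L, pinv = 0) {
  .stop_if(length(rates) != 6L, "GTR needs 6 exchangeabilities")
  ex <- matrix(0, 4, 4)
  ex[lower.tri(ex)] <- rates[c(1L, 2L, 3L, 4L, 5L, 6L)]
  ex <- ex + t(ex)
  substitution_model(alphabet_nt(), ex, freqs, alpha, ncat, pinv, name = "GTR")
}

#' @rdname model_presets
#' @export
model_poisson <- function(alpha = NULL, ncat = 4L, pinv = 0)
  substitution_model(alphabet_aa(), 1, rep(1 / 20, 20), alpha, ncat, pinv,
                     name = "Poisson")

#' @rdname model_presets
#' @export
model_lg <- function(alpha = NULL, ncat = 4L, pinv = 0) {
  lg <- get(".LG", envir = asNamespace("phangorn"))
  ex <- matrix(0, 20, 20)
  ex[lower.tri(ex)] <- lg$Q
  ex <- ex + t(ex)
  substitution_model(alphabet_aa(), ex, unname(lg$bf), alpha, ncat, pinv,
                     name = "LG")
}

#' @rdname model_presets
#' @export
model_dayhoff6 <- function(alpha = NULL, ncat = 4L, pinv = 0)
  substitution_model(alphabet_dayhoff6(), 1, rep(1 / 6, 6), alpha, ncat, pinv,
                     name = "Dayhoff6")

#' @rdname model_presets
#' @export
model_mk2 <- function(q01, q10) {
  .stop_if(!(q01 > 0 && q10 > 0), "trait rates must be > 0")
  pi <- c(q10, q01) / (q01 + q10)
  # exchangeability s with Q01 = s * pi_1 = q01  =>  s = q01 + q10
  substitution_model(alphabet_binary(), q01 + q10, pi, normalize = FALSE,
                     name = "Mk2")
}

#' Rate matrix of a model
#'
#' Builds the generator \eqn{Q} with \eqn{Q_{ij} = s_{ij}\pi_j}, zero row
#' sums, and (for normalised models) unit expected substitution rate at
#' stationarity.
#'
#' @param model a [substitution_model()].
#' @return square numeric matrix.
#' @export
build_rate_matrix <- function(model) {
  stopifnot(inherits(model, "phy_model"))
  Q <- model$exch * rep(model$freqs, each = nrow(model$exch))
  diag(Q) <- -rowSums(Q)
  if (model$normalize) {
    mu <- -sum(model$freqs * diag(Q))
    Q <- Q / mu
  }
  Q
}

## Symmetric eigendecomposition of the reversible generator.
## P(t) = C1 %*% diag(exp(lambda t)) %*% C2 with C1 = D^-1/2 V, C2 = V' D^1/2.
.model_eigen <- function(model) {
  Q <- build_rate_matrix(model)
  d <- sqrt(model$freqs)
  S <- Q * (d / rep(d, each = length(d)))   # D^1/2 Q D^-1/2 (symmetric)
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(lambda = e$values,
       C1 = e$vectors / d,
       C2 = t(e$vectors) * rep(d, each = length(d)),
       pi = model$freqs)
}

.pmat <- function(eig, t) {
  P <- eig$C1 %*% (exp(eig$lambda * t) * eig$C2)
  P[P < 0] <- 0
  P
}

#' Transition probabilities
#'
#' \eqn{P(t) = e^{Qt}} computed from the symmetric eigendecomposition of the
#' reversible generator.
#'
#' @param model a [substitution_model()].
#' @param t branch length, `>= 0`.
#' @return stochastic matrix with rows summing to 1.
#' @export
transition_probabilities <- function(model, t) {
  .stop_if(!(is.numeric(t) && length(t) == 1L && is.finite(t) && t >= 0),
           "branch length must be a single finite value >= 0")
  .pmat(.model_eigen(model), t)
}

#' Discrete-gamma category rates
#'
#' Mean rates of `ncat` equal-probability bins of a Gamma(shape, rate) =
#' (alpha, alpha) distribution, so the category mean is 1.
#'
#' @param alpha gamma shape.
#' @param ncat number of categories.
#' @return numeric vector of length `ncat`, mean 1.
#' @export
discrete_gamma_rates <- function(alpha, ncat) {
  if (ncat == 1L) return(1)
  q <- stats::qgamma(seq(0, 1, length.out = ncat + 1L), alpha, alpha)
  r <- ncat * diff(stats::pgamma(q, alpha + 1, alpha))
  r / mean(r) * 1  # guard against tail rounding; mean(r) is 1 up to fp error
}

## Category rates and weights including the invariant class (rate 0).
.rate_classes <- function(model) {
  if (is.null(model$alpha)) {
    rates <- 1; weights <- 1
  } else {
    rates <- discrete_gamma_rates(model$alpha, model$ncat)
    weights <- rep(1 / model$ncat, model$ncat)
  }
  if (model$pinv > 0) {
    rates <- c(0, rates / (1 - model$pinv))
    weights <- c(model$pinv, weights * (1 - model$pinv))
  }
  list(rates = rates, weights = weights)
}
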