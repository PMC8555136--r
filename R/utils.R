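# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Row-wise log-sum-exp over a list of vectors (one per mixture category).
## `logs` is a matrix with one row per category; returns a vector over columns.
.logsumexp_rows <- function(logs) {
  ncat <- nrow(logs)
  mx <- logs[1L, ]
  if (ncat > 1L) for (i in 2L:ncat) mx <- pmax(mx, logs[i, ])
  acc <- exp(logs[1L, ] - mx)
  if (ncat > 1L) for (i in 2L:ncat) acc <- acc + exp(logs[i, ] - mx)
  mx + log(acc)
}

.stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)

## Deterministic sub-seed derivation: keeps every stage's RNG stream a pure
## function of the user-facing seed while staying inside 32-bit integer range.
.derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483563) + 1L
}

## Column maxima of a numeric matrix without apply() overhead.
.colmax <- function(x) {
  m <- x[1L, ]
  n <- nrow(x)
  if (n > 1L) for (i in 2L:n) m <- pmax(m, x[i, ])
  m
}

.is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x >= 1 && x == round(x)

## Write a data frame as TSV with stable formatting (byte-identical reruns).
.write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1L))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 10, format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
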