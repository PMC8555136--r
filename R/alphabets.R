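#' Character-state alphabets
#'
#' An alphabet is an ordered set of fully specified states plus an ambiguity
#' map sending additional symbols (gaps, `N`/`X`, IUPAC codes, ...) to the
#' subset of states they are compatible with.  Ambiguous symbols enter the
#' likelihood as a partial likelihood of 1 for every compatible state, which
#' makes a gap, an `N` and an `X` all equivalent to "no information" --
#' matching the terminal-gap recoding convention used for transcriptomic
#' supermatrices.
#'
#' @param name short identifier.
#' @param states character vector of single-character state symbols.
#' @param ambig named list mapping additional symbols to integer vectors of
#'   compatible state indices.
#' @return An object of class `phy_alphabet`.
#' @seealso [alphabet_nt()], [alphabet_aa()], [alphabet_dayhoff6()],
#'   [alphabet_binary()]
#' @export
phy_alphabet <- function(name, states, ambig = list()) {
  .stop_if(length(states) < 2L, "an alphabet needs at least 2 states")
  .stop_if(anyDuplicated(states) > 0L, "duplicate state symbols")
  ok <- vapply(ambig, function(s) length(s) >= 1L &&
                 all(s %in% seq_along(states)), logical(1L))
  .stop_if(!all(ok), "ambiguity subsets must be non-empty subsets of states")
  structure(list(name = name, states = as.character(states), ambig = ambig),
            class = "phy_alphabet")
}

#' @export
print.phy_alphabet <- function(x, ...) {
  cat("<phy_alphabet>", x$name, ":", length(x$states), "states [",
      paste(x$states, collapse = ""), "] +", length(x$ambig),
      "ambiguity symbols\n")
  invisible(x)
}

#' @rdname phy_alphabet
#' @details `alphabet_nt()` is A/C/G/T with the IUPAC ambiguity codes;
#'   `N`, `-`, `?` and `X` are fully ambiguous.
#' @export
alphabet_nt <- function() {
  s <- c("A", "C", "G", "T")
  amb <- list(
    R = c(1L, 3L), Y = c(2L, 4L), S = c(2L, 3L), W = c(1L, 4L),
    K = c(3L, 4L), M = c(1L, 2L), B = c(2L, 3L, 4L), D = c(1L, 3L, 4L),
    H = c(1L, 2L, 4L), V = c(1L, 2L, 3L),
    N = 1:4, "-" = 1:4, "?" = 1:4, X = 1:4)
  phy_alphabet("nt", s, amb)
}

#' @rdname phy_alphabet
#' @details `alphabet_aa()` uses the standard 20 amino acids in
#'   ARNDCQEGHILKMFPSTWYV order; `B`, `Z` and `J` are the usual two-state
#'   ambiguities, while `X`, `-`, `?` and `*` carry no information.
#' @export
alphabet_aa <- function() {
  s <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1L]]
  amb <- list(
    B = match(c("N", "D"), s), Z = match(c("Q", "E"), s),
    J = match(c("I", "L"), s),
    X = 1:20, "-" = 1:20, "?" = 1:20, "*" = 1:20)
  phy_alphabet("aa", s, amb)
}

#' @rdname phy_alphabet
#' @details `alphabet_dayhoff6()` has states `1`..`6`, one per Dayhoff group
#'   (AGPST, DENQ, HKR, ILMV, FWY, C).
#' @export
alphabet_dayhoff6 <- function() {
  phy_alphabet("dayhoff6", as.character(1:6),
               list(X = 1:6, "-" = 1:6, "?" = 1:6))
}

#' @rdname phy_alphabet
#' @details `alphabet_binary()` has states `0` (absent) and `1` (present);
#'   `?` and `-` are unknown.
#' @export
alphabet_binary <- function() {
  phy_alphabet("binary", c("0", "1"), list("?" = 1:2, "-" = 1:2))
}

## symbol -> integer state-index set, covering plain states and ambiguities
.state_sets <- function(alphabet) {
  sets <- c(as.list(seq_along(alphabet$states)), alphabet$ambig)
  names(sets) <- c(alphabet$states, names(alphabet$ambig))
  sets
}

## The canonical "no information" symbol used when padding missing taxa.
.missing_symbol <- function(alphabet) {
  switch(alphabet$name, nt = "N", aa = "X", dayhoff6 = "X", binary = "?",
         {
           full <- vapply(alphabet$ambig, function(s)
             length(s) == length(alphabet$states), logical(1L))
           .stop_if(!any(full), "alphabet has no fully ambiguous symbol")
           names(alphabet$ambig)[which(full)[1L]]
         })
}
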