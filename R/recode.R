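#' Six-state Dayhoff recoding
#'
#' Collapses the 20 amino acids onto the six Dayhoff biochemical groups --
#' 1 = AGPST, 2 = DENQ, 3 = HKR, 4 = ILMV, 5 = FWY, 6 = C -- the standard
#' device for reducing saturation and compositional artifacts before
#' parsimony analysis.  Ambiguity and missing symbols map to full ambiguity
#' (`X`); the two-state ambiguities `B` and `Z` fall inside a single group
#' and recode cleanly to `2`.
#'
#' @param aln a [phy_alignment()] on the amino-acid alphabet.
#' @return a [phy_alignment()] on the six-state alphabet.
#' @export
dayhoff6_recode <- function(aln) {
  stopifnot(inherits(aln, "phy_alignment"))
  .stop_if(aln$alphabet$name != "aa",
           "Dayhoff recoding needs an amino-acid alignment, got ",
           aln$alphabet$name)
  groups <- c(A = "1", G = "1", P = "1", S = "1", T = "1",
              D = "2", E = "2", N = "2", Q = "2",
              H = "3", K = "3", R = "3",
              I = "4", L = "4", M = "4", V = "4",
              F = "5", W = "5", Y = "5",
              C = "6",
              B = "2", Z = "2",          # {N,D} and {Q,E} stay in group 2
              J = "4",                   # {I,L}
              X = "X", "-" = "X", "?" = "X", "*" = "X")
  m <- aln$seq
  m[] <- groups[m]
  phy_alignment(m, alphabet_dayhoff6())
}
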