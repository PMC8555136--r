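# Subfamily-level backbone hypotheses for the placement of Chrysomyinae.
#
# One exemplar taxon per blowfly subfamily / related family plus an
# outgroup.  The three competing hypotheses differ only in where
# Chrysomyinae attaches:
#   T1 - Chrysomyinae + Phumosiinae (group 1) sister to all remaining
#        calliphorids,
#   T2 - Chrysomyinae sister to Luciliinae + Calliphorinae + Toxotarsinae
#        (group 3),
#   T3 - Chrysomyinae sister to Rhiniidae + Bengaliinae (group 2b).
# Outside the Chrysomyinae attachment the three trees are identical.

.backbone_taxa <- c("Chrysomyinae", "Phumosiinae", "Ameniinae",
                    "Helicoboscinae", "Rhinophoridae", "Rhiniidae",
                    "Bengaliinae", "Luciliinae", "Calliphorinae",
                    "Toxotarsinae", "Outgroup")

.backbone_groups <- list(
  group1  = c("Chrysomyinae", "Phumosiinae"),
  group2a = c("Ameniinae", "Helicoboscinae", "Rhinophoridae"),
  group2b = c("Rhiniidae", "Bengaliinae"),
  group3  = c("Luciliinae", "Calliphorinae", "Toxotarsinae"),
  outgroup = "Outgroup")

.backbone_newick <- function(hypothesis) {
  core2a <- "((Helicoboscinae,Ameniinae),Rhinophoridae)"
  core2b <- "(Rhiniidae,Bengaliinae)"
  core3 <- "(Luciliinae,(Calliphorinae,Toxotarsinae))"
  switch(hypothesis,
    T1 = sprintf("(Outgroup,((Chrysomyinae,Phumosiinae),(%s,(%s,%s))));",
                 core2a, core2b, core3),
    T2 = sprintf("(Outgroup,(Phumosiinae,(%s,(%s,(Chrysomyinae,%s)))));",
                 core2a, core2b, core3),
    T3 = sprintf("(Outgroup,(Phumosiinae,(%s,((%s,Chrysomyinae),%s))));",
                 core2a, core2b, core3),
    stop("unknown hypothesis id: ", hypothesis, call. = FALSE))
}

#' Backbone topology fixtures T1 / T2 / T3
#'
#' Fixed 11-taxon trees (one exemplar per subfamily-level group plus an
#' outgroup) encoding the three placements of Chrysomyinae, together with
#' the four-cluster group assignment used by likelihood mapping: group 1 =
#' Chrysomyinae + Phumosiinae, group 2a = Ameniinae + Helicoboscinae +
#' Rhinophoridae, group 2b = Rhiniidae + Bengaliinae, group 3 = Luciliinae +
#' Calliphorinae + Toxotarsinae.
#'
#' @param hypothesis one of `"T1"`, `"T2"`, `"T3"`.
#' @param internal_bl internal branch length (substitutions/site).
#' @param terminal_bl terminal branch length.
#' @return object of class `backbone_fixture`: list with `hypothesis`,
#'   `tree` (an [ape::phylo]), and `groups` (named list of taxon sets).
#' @export
backbone_fixture <- function(hypothesis = c("T1", "T2", "T3"),
                             internal_bl = 0.05, terminal_bl = 0.2) {
  hypothesis <- match.arg(hypothesis)
  tree <- parse_newick(.backbone_newick(hypothesis))
  ntip <- length(tree$tip.label)
  tree$edge.length <- ifelse(tree$edge[, 2L] <= ntip, terminal_bl,
                             internal_bl)
  structure(list(hypothesis = hypothesis, tree = tree,
                 groups = .backbone_groups),
            class = "backbone_fixture")
}

#' @export
print.backbone_fixture <- function(x, ...) {
  cat("<backbone_fixture>", x$hypothesis, "-",
      length(x$tree$tip.label), "taxa\n")
  invisible(x)
}
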