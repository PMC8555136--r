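#' Parse a Newick string
#'
#' Thin validating wrapper around [ape::read.tree()].  Before handing the
#' string to the parser, bracket balance and the terminating semicolon are
#' checked so that syntax errors are reported with a character offset.
#' Numeric internal labels are kept as support annotations (`node.label`),
#' quoted labels and `[...]` comments are handled by the underlying reader.
#'
#' @param text a Newick string ending in `;`.
#' @return an [ape::phylo] tree.
#' @export
parse_newick <- function(text) {
  .stop_if(!is.character(text) || length(text) != 1L,
           "text must be a single character string")
  text <- trimws(text)
  .stop_if(!nzchar(text) || substr(text, nchar(text), nchar(text)) != ";",
           "Newick string must end in ';' (offset ", nchar(text), ")")
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  in_quote <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") in_quote <- !in_quote
    if (in_quote) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      .stop_if(depth < 0L, "unbalanced ')' at offset ", i)
    }
  }
  .stop_if(depth != 0L, "unbalanced '(' in Newick string (", depth,
           " unclosed at offset ", nchar(text), ")")
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  .stop_if(is.null(tree), "malformed Newick string")
  validate_tree(tree)
  tree
}

#' Validate a tree object
#'
#' Checks the invariants every tree-consuming stage relies on: unique,
#' non-empty tip labels and finite, non-negative branch lengths (when
#' present).  Zero-length branches are allowed.
#'
#' @param tree an [ape::phylo] object.
#' @return the tree, invisibly.
#' @export
validate_tree <- function(tree) {
  .stop_if(!inherits(tree, "phylo"), "not a phylo object")
  .stop_if(any(!nzchar(tree$tip.label)), "empty tip label")
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  .stop_if(length(dup) > 0L, "duplicate tip label(s): ",
           paste(unique(dup), collapse = ", "))
  if (!is.null(tree$edge.length))
    .stop_if(any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0),
             "branch lengths must be finite and >= 0")
  invisible(tree)
}

#' Write a tree as Newick
#'
#' @param tree an [ape::phylo] object.
#' @param file optional path; when `NULL` the string is returned.
#' @param digits significant digits for branch lengths.
#' @return the Newick string (invisibly when writing to file).
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  s <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Restrict a tree to a taxon subset
#'
#' Induced subtree on `keep`: pruned taxa are removed and the resulting
#' degree-2 nodes are suppressed with their branch lengths summed (the
#' behaviour of [ape::keep.tip()]).  This is the pruning step used by the
#' four-cluster likelihood-mapping variants.
#'
#' @param tree an [ape::phylo] object.
#' @param keep character vector of tip labels to retain, at least 2.
#' @return the induced [ape::phylo] subtree.
#' @export
restrict_to_taxa <- function(tree, keep) {
  keep <- unique(as.character(keep))
  unknown <- setdiff(keep, tree$tip.label)
  .stop_if(length(unknown) > 0L, "unknown tip label(s): ",
           paste(unknown, collapse = ", "))
  .stop_if(length(keep) < 2L, "keep at least 2 taxa")
  if (setequal(keep, tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}

#' Enumerate all unrooted binary topologies
#'
#' All `(2n-5)!!` distinct unrooted binary trees over the given taxa, each
#' exactly once, via [phangorn::allTrees()].  Guarded to `4 <= n <= 9`
#' (135135 trees) because the count explodes beyond that; the exact
#' quartet-score species-tree search relies on this cap.
#'
#' @param taxa character vector of tip labels.
#' @return a `multiPhylo` list of trees without branch lengths.
#' @export
enumerate_unrooted_topologies <- function(taxa) {
  taxa <- sort(unique(as.character(taxa)))
  n <- length(taxa)
  .stop_if(n < 4L || n > 9L,
           "topology enumeration supported for 4..9 taxa, got ", n)
  phangorn::allTrees(n, rooted = FALSE, tip.label = taxa)
}

#' Robinson-Foulds distance
#'
#' Number of non-trivial splits present in exactly one of the two trees
#' (the symmetric-difference count of [phangorn::RF.dist()]); 0 iff both
#' trees have the same unrooted topology.
#'
#' @param t1,t2 trees over identical tip sets.
#' @return non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  .stop_if(!setequal(t1$tip.label, t2$tip.label),
           "trees must share an identical tip set")
  as.integer(phangorn::RF.dist(t1, t2, check.labels = TRUE))
}

#' Non-trivial splits of a tree
#'
#' Each internal edge bipartitions the taxa; the split is keyed by the sorted
#' labels of the side *not* containing the lexicographically smallest taxon,
#' which makes keys comparable across trees and rootings.
#'
#' @param tree an [ape::phylo] object.
#' @return character vector of split keys (`|`-joined sorted labels).
#' @export
tree_splits <- function(tree) {
  tips <- tree$tip.label
  n <- length(tips)
  if (n < 4L) return(character())
  anchor <- sort(tips)[1L]
  bp <- ape::prop.part(ape::unroot(tree))
  labs <- attr(bp, "labels")
  keys <- character(0)
  for (part in bp) {
    side <- labs[part]
    if (length(side) < 2L || length(side) > n - 2L) next
    if (anchor %in% side) side <- setdiff(tips, side)
    if (length(side) < 2L) next
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Clade constraints
#'
#' A constraint is a set of tip labels required to be monophyletic on some
#' rooting of the tree, i.e. to form one side of a split.
#'
#' @param labels character vector of tip labels, length >= 2.
#' @return an object of class `clade_constraint`.
#' @export
clade_constraint <- function(labels) {
  labels <- unique(as.character(labels))
  .stop_if(length(labels) < 2L, "a clade constraint needs >= 2 taxa")
  structure(labels, class = "clade_constraint")
}

#' Test whether a tree satisfies clade constraints
#'
#' `TRUE` iff every constraint set appears as a split of the unrooted tree
#' (sets of size `n-1` or `n` are trivially satisfied).
#'
#' @param tree an [ape::phylo] object.
#' @param constraints a [clade_constraint()] or list of them (plain character
#'   vectors are accepted).
#' @return logical scalar.
#' @export
satisfies_constraints <- function(tree, constraints) {
  if (!is.list(constraints) || inherits(constraints, "clade_constraint"))
    constraints <- list(constraints)
  tips <- tree$tip.label
  n <- length(tips)
  anchor <- sort(tips)[1L]
  keys <- tree_splits(tree)
  for (con in constraints) {
    con <- unique(as.character(con))
    bad <- setdiff(con, tips)
    .stop_if(length(bad) > 0L, "constraint labels not in tree: ",
             paste(bad, collapse = ", "))
    if (length(con) <= 1L || length(con) >= n - 1L) next  # trivially a split
    side <- if (anchor %in% con) setdiff(tips, con) else con
    key <- paste(sort(side), collapse = "|")
    if (!key %in% keys) return(FALSE)
  }
  TRUE
}

#' Export splits as a TSV of bipartitions
#'
#' One row per non-trivial split with both sides spelled out.
#'
#' @param tree an [ape::phylo] object.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_splits_tsv <- function(tree, file) {
  keys <- tree_splits(tree)
  side1 <- keys
  side2 <- vapply(keys, function(k) {
    paste(sort(setdiff(tree$tip.label, strsplit(k, "|", fixed = TRUE)[[1L]])),
          collapse = "|")
  }, character(1L))
  .write_tsv(data.frame(split = side1, complement = side2,
                        stringsAsFactors = FALSE), file)
}
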