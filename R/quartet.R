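# Quartet-score species-tree estimation from gene trees.
#
# The quartet score of a candidate species tree is the number of (gene
# tree, taxon quadruple) combinations whose induced quartet topology
# matches the candidate's.  At the subfamily-exemplar scale used here
# (<= 9 taxa) the maximiser is found by exhaustive enumeration of all
# unrooted topologies, replacing the heuristic search of scalable
# quartet-score tools.

## topology id of quadruple (t1<t2<t3<t4) in a tree: 1 = t1t2|t3t4,
## 2 = t1t3|t2t4, 3 = t1t4|t2t3, 0 = unresolved.  Table over all
## quadruples of `taxa` present in the tree, via the tree's splits.
.quartet_table <- function(tree, taxa) {
  present <- intersect(taxa, tree$tip.label)
  if (length(present) < 4L) return(NULL)
  present <- sort(present)
  quads <- utils::combn(present, 4L)
  ## membership of each tip in each split side
  keys <- tree_splits(tree)
  topo <- integer(ncol(quads))
  if (length(keys) > 0L) {
    sides <- lapply(keys, function(k) strsplit(k, "|", fixed = TRUE)[[1L]])
    memb <- vapply(sides, function(s) present %in% s,
                   logical(length(present)))  # taxa x splits
    rownames(memb) <- present
    for (q in seq_len(ncol(quads))) {
      four <- quads[, q]
      m <- memb[four, , drop = FALSE]
      cs <- colSums(m)
      cand <- which(cs == 2L)
      for (s in cand) {
        pairmask <- m[, s]
        ## which of t2..t4 is grouped with t1
        with1 <- if (pairmask[1L]) which(pairmask[-1L]) else
          which(!pairmask[-1L])
        if (length(with1) == 1L) {
          topo[q] <- with1
          break
        }
      }
    }
  }
  list(quads = quads, topo = topo,
       key = apply(quads, 2L, paste, collapse = "|"))
}

#' Quartet agreement score
#'
#' Total number of taxon quadruples, summed over gene trees, whose induced
#' quartet topology agrees with the species tree.  Gene trees may miss taxa
#' (they contribute fewer quadruples) and polytomies contribute no resolved
#' quartets; gene trees with fewer than 4 tips contribute 0.
#'
#' @param species_tree candidate species tree.
#' @param gene_trees list (or `multiPhylo`) of gene trees with tip sets
#'   within the species tree's.
#' @return integer score.
#' @export
quartet_agreement_score <- function(species_tree, gene_trees) {
  taxa <- species_tree$tip.label
  for (g in gene_trees)
    .stop_if(length(setdiff(g$tip.label, taxa)) > 0L,
             "gene tree contains taxa absent from the species tree")
  st <- .quartet_table(species_tree, taxa)
  .stop_if(is.null(st), "species tree needs at least 4 taxa")
  ref <- stats::setNames(st$topo, st$key)
  score <- 0L
  for (g in gene_trees) {
    gt <- .quartet_table(g, taxa)
    if (is.null(gt)) next
    match_topo <- ref[gt$key]
    score <- score + sum(gt$topo > 0L & gt$topo == match_topo)
  }
  as.integer(score)
}

#' Exact quartet-score species tree
#'
#' Maximises [quartet_agreement_score()] over all unrooted binary
#' topologies on the given taxa (exhaustive; capped at 9 taxa).  All
#' co-optimal trees are returned.
#'
#' @param gene_trees list of gene trees.
#' @param taxa species-tree taxon set (4 to 9 labels).
#' @return list with `trees` (a `multiPhylo` of co-optimal topologies) and
#'   `score` (the maximal quartet score).
#' @export
exact_quartet_species_tree <- function(gene_trees, taxa) {
  taxa <- sort(unique(as.character(taxa)))
  candidates <- enumerate_unrooted_topologies(taxa)  # guards 4..9
  ## aggregate gene-tree quartet counts: quad key x topology id
  counts <- new.env(parent = emptyenv())
  for (g in gene_trees) {
    gt <- .quartet_table(g, taxa)
    if (is.null(gt)) next
    for (q in seq_along(gt$topo)) {
      if (gt$topo[q] == 0L) next
      k <- gt$key[q]
      cur <- counts[[k]] %||% c(0L, 0L, 0L)
      cur[gt$topo[q]] <- cur[gt$topo[q]] + 1L
      counts[[k]] <- cur
    }
  }
  score_of <- vapply(candidates, function(cand) {
    ct <- .quartet_table(cand, taxa)
    s <- 0L
    for (q in seq_along(ct$topo)) {
      cur <- counts[[ct$key[q]]]
      if (!is.null(cur) && ct$topo[q] > 0L) s <- s + cur[ct$topo[q]]
    }
    s
  }, integer(1L))
  best <- which(score_of == max(score_of))
  trees <- candidates[best]
  class(trees) <- "multiPhylo"
  list(trees = trees, score = as.integer(max(score_of)))
}

#' Gene-tree resampling support for the quartet species tree
#'
#' Runs the exact quartet-score search on each replicate collection of gene
#' trees; the support of each split of the main estimate is the percentage
#' of replicate sets whose optimum contains it (with co-optimal replicate
#' trees, the split must be in all of them to count).
#'
#' @param gene_tree_replicate_sets list of gene-tree collections, one per
#'   bootstrap replicate.
#' @param taxa species-tree taxon set (4 to 9 labels).
#' @param main_tree the point estimate whose splits are annotated; when
#'   `NULL`, the exact search on the pooled gene trees of all sets is used
#'   (first co-optimum).
#' @return a `support_map` data frame (`split`, `support` in percent) with
#'   the main tree in `attr(, "tree")`.
#' @export
gene_tree_bootstrap_support <- function(gene_tree_replicate_sets, taxa,
                                        main_tree = NULL) {
  .stop_if(length(gene_tree_replicate_sets) == 0L, "no replicate sets")
  if (is.null(main_tree)) {
    pooled <- do.call(c, lapply(gene_tree_replicate_sets, function(s)
      unclass(s)))
    main_tree <- exact_quartet_species_tree(pooled, taxa)$trees[[1L]]
  }
  ref_splits <- tree_splits(main_tree)
  hits <- stats::setNames(numeric(length(ref_splits)), ref_splits)
  for (set in gene_tree_replicate_sets) {
    opt <- exact_quartet_species_tree(set, taxa)$trees
    common <- Reduce(intersect, lapply(opt, tree_splits))
    hits[ref_splits %in% common] <- hits[ref_splits %in% common] + 1
  }
  structure(data.frame(split = ref_splits,
                       support = unname(100 * hits /
                                          length(gene_tree_replicate_sets)),
                       stringsAsFactors = FALSE),
            class = c("support_map", "data.frame"),
            tree = main_tree)
}
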