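# Fitch parsimony with ambiguity-set tip states, NNI hill-climbing, and
# jackknife support.  State sets are integer bitmasks, so the per-site
# Fitch pass is a handful of vectorised bit operations over all site
# patterns at once.

## taxa x patterns bitmask matrix + pattern weights
.fitch_masks <- function(aln) {
  sets <- .state_sets(aln$alphabet)
  .stop_if(length(aln$alphabet$states) > 30L,
           "bitmask Fitch supports at most 30 states")
  bit_of <- vapply(sets, function(s) sum(bitwShiftL(1L, s - 1L)), numeric(1L))
  pat <- .pattern_compress(aln$seq)
  masks <- matrix(as.integer(bit_of[pat$mat]), nrow(pat$mat), ncol(pat$mat))
  rownames(masks) <- rownames(pat$mat)
  list(masks = masks, w = pat$w)
}

## Fitch pass over a rooted binary resolution of the tree; sequential
## pairwise combination at the (possibly trifurcating) root of an unrooted
## tree is exact because it equals rooting along one of its edges.
.fitch_count <- function(tree, masks, w) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  npat <- ncol(masks)
  state <- vector("list", ntip + tr$Nnode)
  ord <- match(tr$tip.label, rownames(masks))
  changes <- numeric(npat)
  parents <- unique(tr$edge[, 1L])
  for (nd in parents) {
    rows <- which(tr$edge[, 1L] == nd)
    acc <- NULL
    for (r in rows) {
      ch <- tr$edge[r, 2L]
      cm <- if (ch <= ntip) masks[ord[ch], ] else state[[ch]]
      if (is.null(acc)) {
        acc <- cm
      } else {
        inter <- bitwAnd(acc, cm)
        zero <- inter == 0L
        changes <- changes + zero
        acc <- ifelse(zero, bitwOr(acc, cm), inter)
      }
    }
    state[[nd]] <- acc
  }
  sum(w * changes)
}

#' Fitch parsimony score
#'
#' Minimum number of state changes over the tree summed across sites, with
#' ambiguity sets used directly as tip state sets (so gaps and missing data
#' cost nothing on their own, and all-missing sites contribute 0).
#'
#' @param tree unrooted binary [ape::phylo] (a rooted binary tree scores
#'   identically).
#' @param aln a [phy_alignment()]; tree tips must be among its taxa.
#' @return integer score.
#' @export
fitch_score <- function(tree, aln) {
  missing <- setdiff(tree$tip.label, aln_taxa(aln))
  .stop_if(length(missing) > 0L, "taxa in tree but not in alignment: ",
           paste(missing, collapse = ", "))
  fm <- .fitch_masks(.aln_subset(aln, taxa = tree$tip.label))
  as.integer(round(.fitch_count(tree, fm$masks, fm$w)))
}

#' Parsimony hill-climbing over nearest-neighbour interchanges
#'
#' Greedy NNI search: from the starting tree, move to the best-scoring NNI
#' neighbour while any neighbour improves the Fitch score, breaking ties
#' among equally best improving moves at random (seeded).  The returned
#' score is never worse than the start's.
#'
#' @param aln a [phy_alignment()].
#' @param start starting tree over the alignment's taxa.
#' @param seed integer seed for tie-breaking.
#' @return the locally optimal tree, with its score in `attr(, "score")`
#'   and the accepted-score trajectory in `attr(, "trajectory")`.
#' @export
parsimony_search_nni <- function(aln, start, seed = 1L) {
  fm <- .fitch_masks(.aln_subset(aln, taxa = start$tip.label))
  set.seed(seed)
  cur <- ape::unroot(start)
  cur_score <- .fitch_count(cur, fm$masks, fm$w)
  traj <- cur_score
  repeat {
    nb <- phangorn::nni(cur)
    scores <- vapply(nb, .fitch_count, numeric(1L), masks = fm$masks,
                     w = fm$w)
    if (min(scores) >= cur_score) break
    besties <- which(scores == min(scores))
    pick <- if (length(besties) == 1L) besties else
      besties[sample.int(length(besties), 1L)]
    cur <- nb[[pick]]
    cur_score <- scores[pick]
    traj <- c(traj, cur_score)
  }
  attr(cur, "score") <- as.integer(round(cur_score))
  attr(cur, "trajectory") <- as.integer(round(traj))
  cur
}

## random unrooted starting topology
.random_topology <- function(taxa, tmp_seedless = FALSE) {
  tr <- ape::rtree(length(taxa), rooted = FALSE,
                   tip.label = sample(taxa))
  tr$edge.length <- NULL
  tr
}

#' Jackknife support for parsimony splits
#'
#' The full-data tree is estimated by multi-start NNI; each jackknife
#' replicate deletes every site independently with the given probability
#' (a replicate that loses all sites is redrawn), re-runs a single seeded
#' NNI search from a random start, and the support of each full-data split
#' is the percentage of replicate trees containing it.
#'
#' @param aln a [phy_alignment()].
#' @param deletion per-site deletion probability in (0, 1); 0.36 is the
#'   convention associated with parsimony jackknifing.
#' @param replicates number of jackknife replicates.
#' @param seed integer seed.
#' @param n_starts NNI starts for the full-data search.
#' @return object of class `support_map`: data frame with columns `split`
#'   and `support` (percent); the annotated best tree is kept in
#'   `attr(, "tree")`, the number of redrawn replicates in
#'   `attr(, "redrawn")`.
#' @export
jackknife_support <- function(aln, deletion = 0.36, replicates = 1000L,
                              seed = 1L, n_starts = 10L) {
  .stop_if(!(deletion > 0 && deletion < 1), "deletion must be in (0, 1)")
  .stop_if(!.is_count(replicates), "replicates must be >= 1")
  taxa <- aln_taxa(aln)
  ## full-data tree: best of n_starts seeded NNI searches
  best <- NULL
  for (s in seq_len(n_starts)) {
    set.seed(.derive_seed(seed, 1000L + s))
    cand <- parsimony_search_nni(aln, .random_topology(taxa),
                                 seed = .derive_seed(seed, 2000L + s))
    if (is.null(best) || attr(cand, "score") < attr(best, "score"))
      best <- cand
  }
  ref_splits <- tree_splits(best)
  hits <- stats::setNames(numeric(length(ref_splits)), ref_splits)
  n <- aln_nsites(aln)
  redrawn <- 0L
  for (b in seq_len(replicates)) {
    set.seed(.derive_seed(seed, 3000L + b))
    keep <- which(stats::runif(n) >= deletion)
    while (length(keep) == 0L) {
      redrawn <- redrawn + 1L
      keep <- which(stats::runif(n) >= deletion)
    }
    sub <- .aln_subset(aln, sites = keep)
    tr <- parsimony_search_nni(sub, .random_topology(taxa),
                               seed = .derive_seed(seed, 4000L + b))
    sp <- tree_splits(tr)
    hits[ref_splits %in% sp] <- hits[ref_splits %in% sp] + 1
  }
  support <- 100 * hits / replicates
  structure(data.frame(split = ref_splits, support = unname(support),
                       stringsAsFactors = FALSE),
            class = c("support_map", "data.frame"),
            tree = best, redrawn = redrawn, replicates = replicates,
            deletion = deletion, seed = seed)
}
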