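# Four-cluster likelihood mapping (FcLM).
#
# Quartets are drawn one taxon per group.  For each quartet the three
# resolved topologies are scored by maximum likelihood on that quartet's
# alignment columns (branch lengths optimised per quartet), the scores are
# softmax-normalised into posterior weights (w1, w2, w3) on the 2-simplex,
# and each quartet is assigned to the basin (argmax) of one grouping
# hypothesis.  A 7-region breakdown (3 corners, 3 edges, 1 centre) refines
# the same weights: corner i iff w_i >= 2/3; otherwise an edge between the
# two largest weights iff the smallest weight <= 1/6; otherwise centre.

## the three resolved topologies of a quartet (a,b,c,d), as the pairing of
## the first taxon: 1 = ab|cd, 2 = ac|bd, 3 = ad|bc
.quartet_trees <- function(taxa, bl = 0.1) {
  mk <- function(x1, x2, x3, x4)
    parse_newick(sprintf("((%s:%g,%s:%g):%g,(%s:%g,%s:%g):%g);",
                         x1, bl, x2, bl, bl, x3, bl, x4, bl, bl))
  list(mk(taxa[1L], taxa[2L], taxa[3L], taxa[4L]),
       mk(taxa[1L], taxa[3L], taxa[2L], taxa[4L]),
       mk(taxa[1L], taxa[4L], taxa[2L], taxa[3L]))
}

.fclm_region <- function(w) {
  i <- which.max(w)
  if (w[i] >= 2 / 3) return(paste0("corner", i))
  if (min(w) <= 1 / 6) {
    two <- order(w, decreasing = TRUE)[1:2]
    return(paste0("edge", paste(sort(two), collapse = "")))
  }
  "center"
}

#' Four-cluster likelihood mapping
#'
#' @param aln a [phy_alignment()].
#' @param groups named list of four disjoint, non-empty taxon sets; the
#'   three basins correspond to pairing group 1 with group 2, 3 or 4
#'   (`w1 = g1+g2 | g3+g4`, `w2 = g1+g3 | g2+g4`, `w3 = g1+g4 | g2+g3`).
#' @param model a [substitution_model()].
#' @param max_quartets evaluate all quartets if their number is at most
#'   this, otherwise sample that many uniformly without replacement.
#' @param seed integer seed (used only when sampling).
#' @param min_sites quartets with fewer unambiguous all-four-taxa sites are
#'   skipped and counted as dropped.
#' @param bl_tol,bl_cycles convergence tolerance and sweep cap for the
#'   per-quartet branch-length optimisation.  Quartet weights are a softmax
#'   over log-likelihood differences that are typically orders of magnitude
#'   above 0.001, so the default tolerance is looser than the engine-wide
#'   one.
#' @return object of class `fclm_result`: per-quartet weight table,
#'   basin/region counts and percentages, basin hypothesis labels, dropped
#'   count.
#' @export
fclm <- function(aln, groups, model, max_quartets = 10000L, seed = 1L,
                 min_sites = 10L, bl_tol = 1e-3, bl_cycles = 3L) {
  .stop_if(length(groups) != 4L, "need exactly four groups")
  .stop_if(is.null(names(groups)), "groups must be named")
  .stop_if(any(lengths(groups) == 0L), "each group must be non-empty")
  all_members <- unlist(groups, use.names = FALSE)
  .stop_if(anyDuplicated(all_members) > 0L, "groups must be disjoint")
  absent <- setdiff(all_members, aln_taxa(aln))
  .stop_if(length(absent) > 0L, "group members not in alignment: ",
           paste(absent, collapse = ", "))
  quartets <- as.matrix(expand.grid(groups, stringsAsFactors = FALSE,
                                    KEEP.OUT.ATTRS = FALSE))
  if (nrow(quartets) > max_quartets) {
    set.seed(seed)
    quartets <- quartets[sample.int(nrow(quartets), max_quartets), ,
                         drop = FALSE]
  }
  sets <- .state_sets(aln$alphabet)
  unambig <- names(sets)[lengths(sets) == 1L]
  lab <- function(i, j) {
    nm <- names(groups)
    o <- setdiff(1:4, c(i, j))
    paste0(nm[i], "+", nm[j], " | ", nm[o[1L]], "+", nm[o[2L]])
  }
  hyp <- c(lab(1L, 2L), lab(1L, 3L), lab(1L, 4L))
  rows <- vector("list", nrow(quartets))
  dropped <- 0L
  for (q in seq_len(nrow(quartets))) {
    taxa <- as.character(quartets[q, ])
    sub <- .aln_subset(aln, taxa = taxa)
    ok <- colSums(matrix(sub$seq %in% unambig, nrow = 4L)) == 4L
    if (sum(ok) < min_sites) {
      dropped <- dropped + 1L
      next
    }
    lls <- vapply(.quartet_trees(taxa), function(tr)
      attr(optimize_branch_lengths(tr, sub, model, tol = bl_tol,
                                   max_cycles = bl_cycles), "loglik"),
      numeric(1L))
    w <- exp(lls - max(lls))
    w <- w / sum(w)
    rows[[q]] <- data.frame(t(stats::setNames(taxa, names(groups))),
                            w1 = w[1L], w2 = w[2L], w3 = w[3L],
                            basin = which.max(w),
                            region = .fclm_region(w),
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  n_eval <- if (is.null(tab)) 0L else nrow(tab)
  .stop_if(n_eval == 0L, "all quartets were dropped (too little overlap)")
  basin_counts <- stats::setNames(tabulate(tab$basin, 3L), hyp)
  region_names <- c("corner1", "corner2", "corner3",
                    "edge12", "edge13", "edge23", "center")
  region_counts <- stats::setNames(
    vapply(region_names, function(r) sum(tab$region == r), integer(1L)),
    region_names)
  structure(list(quartets = tab,
                 n_quartets = n_eval,
                 dropped = dropped,
                 hypotheses = hyp,
                 basin_counts = basin_counts,
                 basin_percent = 100 * basin_counts / n_eval,
                 region_counts = region_counts,
                 region_percent = 100 * region_counts / n_eval,
                 seed = seed),
            class = "fclm_result")
}

#' @export
print.fclm_result <- function(x, ...) {
  cat("<fclm_result>", x$n_quartets, "quartets evaluated,", x$dropped,
      "dropped\n")
  for (i in 1:3)
    cat(sprintf("  %5.1f%%  %s\n", x$basin_percent[i], x$hypotheses[i]))
  invisible(x)
}

#' Paraphyly-aware FcLM variants
#'
#' When one of the four clusters is paraphyletic, FcLM is not applicable
#' directly; instead the offending cluster is split (here into groups 2a
#' and 2b) and the mapping is run twice, once with each half pruned from
#' the alignment.  Only the four active groups are retained in each run,
#' since quartets are drawn solely from group members.  In both variants
#' the basins are labelled with the grouping hypothesis they support;
#' `group1 + outgroup` corresponds to group 1 being sister to all remaining
#' calliphorids.
#'
#' @inheritParams fclm
#' @param group1,group2a,group2b,group3 taxon sets (see
#'   [backbone_fixture()] for the canonical assignment).
#' @param outgroup taxa used as the fourth cluster in both variants.
#' @return list with elements `without_2b` and `without_2a`, each an
#'   [fclm()] result.
#' @export
fclm_paraphyly_variants <- function(aln, group1, group2a, group2b, group3,
                                    outgroup, model, max_quartets = 10000L,
                                    seed = 1L, bl_tol = 1e-3,
                                    bl_cycles = 3L) {
  a <- fclm(.aln_subset(aln, taxa = setdiff(aln_taxa(aln), group2b)),
            list(group1 = group1, group2a = group2a, group3 = group3,
                 outgroup = outgroup),
            model, max_quartets, .derive_seed(seed, 1L),
            bl_tol = bl_tol, bl_cycles = bl_cycles)
  b <- fclm(.aln_subset(aln, taxa = setdiff(aln_taxa(aln), group2a)),
            list(group1 = group1, group2b = group2b, group3 = group3,
                 outgroup = outgroup),
            model, max_quartets, .derive_seed(seed, 2L),
            bl_tol = bl_tol, bl_cycles = bl_cycles)
  list(without_2b = a, without_2a = b)
}

#' Write FcLM per-quartet weights as TSV (ternary-plot coordinates)
#'
#' @param result an [fclm()] result.
#' @param file output path.
#' @export
write_fclm_tsv <- function(result, file) {
  stopifnot(inherits(result, "fclm_result"))
  .write_tsv(result$quartets, file)
}
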