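# Seeded generators emulating the statistical structure of a multi-gene
# transcriptomic supermatrix: per-gene rate variation, taxon-wise missing
# data, coalescent gene-tree discordance, and a binary trait evolving on
# the tree.  Every generator is a pure function of (inputs, seed).

#' Simulate an alignment on a tree
#'
#' Root states are drawn from the model's equilibrium frequencies, a rate
#' class is drawn per site, and states evolve down each branch by the
#' model's transition probabilities.
#'
#' @param tree rooted or unrooted [ape::phylo] with branch lengths.
#' @param model a [substitution_model()].
#' @param n_sites number of sites, `>= 1`.
#' @param seed integer seed; identical inputs give bit-identical output.
#' @return a [phy_alignment()] over the tree's tips.
#' @export
simulate_alignment <- function(tree, model, n_sites, seed) {
  validate_tree(tree)
  .stop_if(is.null(tree$edge.length) || anyNA(tree$edge.length),
           "missing branch length")
  .stop_if(!.is_count(n_sites), "n_sites must be a positive integer")
  set.seed(seed)
  rc <- .rate_classes(model)
  eig <- .model_eigen(model)
  nst <- length(model$alphabet$states)
  ntip <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  cats <- sample.int(length(rc$rates), n_sites, replace = TRUE,
                     prob = rc$weights)
  states <- matrix(0L, ntip + tr$Nnode, n_sites)
  root <- ntip + 1L
  states[root, ] <- sample.int(nst, n_sites, replace = TRUE,
                               prob = model$freqs)
  # preorder = reversed postorder edges
  for (r in rev(seq_len(nrow(tr$edge)))) {
    par <- tr$edge[r, 1L]
    ch <- tr$edge[r, 2L]
    t <- tr$edge.length[r]
    for (cat in unique(cats)) {
      P <- .pmat(eig, t * rc$rates[cat])
      for (s in seq_len(nst)) {
        idx <- which(cats == cat & states[par, ] == s)
        if (length(idx) > 0L)
          states[ch, idx] <- sample.int(nst, length(idx), replace = TRUE,
                                        prob = P[s, ])
      }
    }
  }
  mat <- matrix(model$alphabet$states[states[seq_len(ntip), , drop = FALSE]],
                ntip, n_sites)
  rownames(mat) <- tr$tip.label
  phy_alignment(mat, model$alphabet)
}

#' Gene specifications for supermatrix simulation
#'
#' A `gene_spec` records a gene's name, length, relative evolutionary rate,
#' and the taxa it is missing from.  `sample_gene_specs()` draws a set of
#' them emulating a transcriptomic supermatrix: the defaults mirror a
#' 2221-gene amino-acid matrix with roughly 0.71 data completeness and
#' log-normal among-gene rate variation.
#'
#' @param name gene name.
#' @param length sites, `>= 1`.
#' @param rate positive rate multiplier applied to every branch.
#' @param missing character vector of taxa without data for this gene.
#' @return `gene_spec()`: one spec; `sample_gene_specs()`: a list of specs.
#' @export
gene_spec <- function(name, length, rate = 1, missing = character()) {
  .stop_if(!.is_count(length), "gene length must be >= 1")
  .stop_if(!(is.numeric(rate) && rate > 0), "rate multiplier must be > 0")
  structure(list(name = as.character(name), length = as.integer(length),
                 rate = rate, missing = as.character(missing)),
            class = "gene_spec")
}

#' @rdname gene_spec
#' @param n_genes number of genes.
#' @param taxa taxon labels missingness is drawn over.
#' @param mean_length mean gene length in sites.
#' @param rate_sd standard deviation of log rate multipliers (mean 1 on the
#'   natural scale).
#' @param completeness expected fraction of taxon-gene cells present.
#' @param seed integer seed.
#' @export
sample_gene_specs <- function(n_genes = 2221L, taxa, mean_length = 536L,
                              rate_sd = 0.4, completeness = 0.709, seed = 1L) {
  .stop_if(completeness <= 0 || completeness > 1,
           "completeness must be in (0, 1]")
  set.seed(seed)
  lens <- pmax(30L, round(stats::rlnorm(n_genes,
                                        log(mean_length) - 0.125, 0.5)))
  rates <- stats::rlnorm(n_genes, -rate_sd^2 / 2, rate_sd)
  lapply(seq_len(n_genes), function(i) {
    miss <- taxa[stats::runif(length(taxa)) > completeness]
    if (length(miss) >= length(taxa))  # keep at least one taxon with data
      miss <- miss[-sample.int(length(miss), 1L)]
    gene_spec(sprintf("gene%04d", i), lens[i], rates[i], miss)
  })
}

#' Simulate a partitioned supermatrix
#'
#' Each gene is simulated on the tree with branch lengths scaled by its rate
#' multiplier; taxa listed as missing get the alphabet's fully ambiguous
#' symbol for the whole gene block.  Genes are concatenated in the order
#' given and the partition intervals recorded.
#'
#' @inheritParams simulate_alignment
#' @param genes list of [gene_spec()]s with unique names.
#' @return list with `alignment` (a [phy_alignment()]) and `partitions`
#'   (a [partition_map()]).
#' @export
simulate_supermatrix <- function(tree, genes, model, seed) {
  nms <- vapply(genes, `[[`, character(1L), "name")
  .stop_if(anyDuplicated(nms) > 0L, "gene names must be unique")
  for (g in genes)
    .stop_if(length(setdiff(tree$tip.label, g$missing)) == 0L,
             "gene ", g$name, " is missing all taxa")
  gap <- .missing_symbol(model$alphabet)
  blocks <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    tg <- tree
    tg$edge.length <- tree$edge.length * g$rate
    sub <- simulate_alignment(tg, model, g$length, .derive_seed(seed, i))
    m <- sub$seq[tree$tip.label, , drop = FALSE]
    if (length(g$missing) > 0L)
      m[intersect(g$missing, rownames(m)), ] <- gap
    blocks[[i]] <- m
  }
  aln <- phy_alignment(do.call(cbind, blocks), model$alphabet)
  list(alignment = aln,
       partitions = partition_map(nms, vapply(genes, `[[`, integer(1L),
                                              "length")))
}

#' Simulate gene trees under the multispecies coalescent
#'
#' One haploid lineage per species; within each species-tree branch (lengths
#' in coalescent units) lineages merge with exponential waiting times at
#' rate `k(k-1)/2`, and remaining lineages coalesce freely above the root.
#'
#' @param species_tree rooted binary [ape::phylo] with branch lengths in
#'   coalescent units.
#' @param n_loci number of independent gene trees.
#' @param seed integer seed.
#' @return a `multiPhylo` list of rooted gene trees with branch lengths in
#'   coalescent units.
#' @export
simulate_gene_trees_msc <- function(species_tree, n_loci, seed) {
  validate_tree(species_tree)
  .stop_if(!ape::is.rooted(species_tree), "species tree must be rooted")
  .stop_if(!ape::is.binary(species_tree), "species tree must be binary")
  .stop_if(is.null(species_tree$edge.length), "missing branch lengths")
  set.seed(seed)
  tr <- ape::reorder.phylo(species_tree, "postorder")
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  trees <- vector("list", n_loci)
  for (locus in seq_len(n_loci)) {
    ## Each species-tree branch runs on its own local clock (coalescent-unit
    ## branch lengths need not be ultrametric).  A lineage carries `pend`,
    ## the coalescent time accumulated since its last node; merging at local
    ## offset tau closes both child edges at pend + tau.
    n_nodes <- ntip + tr$Nnode
    pool <- vector("list", n_nodes)
    for (i in seq_len(ntip)) pool[[i]] <- list(id = i, pend = 0)
    next_id <- ntip + 1L
    merges <- matrix(0L, ntip - 1L, 2L)
    elens <- matrix(0, ntip - 1L, 2L)
    mrow <- 0L
    run_branch <- function(lin, duration) {
      k <- length(lin$id)
      tau <- 0
      while (k > 1L) {
        w <- stats::rexp(1L, k * (k - 1L) / 2)
        if (tau + w > duration) break
        tau <- tau + w
        pick <- sample.int(k, 2L)
        mrow <<- mrow + 1L
        merges[mrow, ] <<- lin$id[pick]
        elens[mrow, ] <<- lin$pend[pick] + tau
        keep <- setdiff(seq_len(k), pick)
        lin <- list(id = c(lin$id[keep], next_id),
                    pend = c(lin$pend[keep], -tau))
        next_id <<- next_id + 1L
        k <- k - 1L
      }
      lin$pend <- lin$pend + duration
      lin
    }
    for (r in seq_len(nrow(tr$edge))) {
      ch <- tr$edge[r, 2L]
      par <- tr$edge[r, 1L]
      lin <- run_branch(pool[[ch]], tr$edge.length[r])
      pool[[par]] <- if (is.null(pool[[par]])) lin else
        list(id = c(pool[[par]]$id, lin$id),
             pend = c(pool[[par]]$pend, lin$pend))
    }
    run_branch(pool[[root]], Inf)
    trees[[locus]] <- .build_coal_tree(merges, elens, ntip, tr$tip.label)
  }
  class(trees) <- "multiPhylo"
  trees
}

## assemble an ape tree from coalescence records (merge i creates internal
## node ntip+i in chronological order; ape wants the root, i.e. the last
## merge, at ntip+1, so internal ids are remapped ntip+i -> 2*ntip - i)
.build_coal_tree <- function(merges, elens, ntip, tip_labels) {
  n_int <- ntip - 1L
  remap <- function(id) ifelse(id <= ntip, id, 2L * ntip - (id - ntip))
  edge <- matrix(0L, 2L * n_int, 2L)
  elen <- numeric(2L * n_int)
  row <- 0L
  for (i in seq_len(n_int)) {
    parent <- remap(ntip + i)
    for (j in 1:2) {
      row <- row + 1L
      edge[row, ] <- c(parent, remap(merges[i, j]))
      elen[row] <- elens[i, j]
    }
  }
  tree <- structure(list(edge = edge, edge.length = elen,
                         tip.label = tip_labels, Nnode = n_int),
                    class = "phylo")
  ape::reorder.phylo(tree, "cladewise")
}

#' Simulate a binary trait by event simulation
#'
#' The root state is drawn from the stationary distribution
#' `(q10, q01) / (q01 + q10)`; each branch is then simulated event-by-event
#' (Gillespie), which yields exact endpoint states plus the realised number
#' of changes per branch.
#'
#' @param tree rooted [ape::phylo] with branch lengths.
#' @param q01 gain rate (0 to 1), `> 0`.
#' @param q10 loss rate (1 to 0), `> 0`.
#' @param seed integer seed.
#' @return list with `tip_states` (named 0/1 integer vector),
#'   `node_states` (internal nodes, by ape node id), and `branch_changes`
#'   (events per edge, in the tree's edge order).
#' @export
simulate_binary_trait <- function(tree, q01, q10, seed) {
  validate_tree(tree)
  .stop_if(!(q01 > 0 && q10 > 0), "rates must be > 0")
  .stop_if(is.null(tree$edge.length), "missing branch lengths")
  set.seed(seed)
  ntip <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  states <- integer(ntip + tr$Nnode)
  root <- ntip + 1L
  pi1 <- q01 / (q01 + q10)
  states[root] <- stats::rbinom(1L, 1L, pi1)
  changes <- integer(nrow(tr$edge))
  rate_of <- c(q01, q10)  # leaving state 0, state 1
  for (r in rev(seq_len(nrow(tr$edge)))) {
    s <- states[tr$edge[r, 1L]]
    t_left <- tr$edge.length[r]
    k <- 0L
    repeat {
      wait <- stats::rexp(1L, rate_of[s + 1L])
      if (wait > t_left) break
      t_left <- t_left - wait
      s <- 1L - s
      k <- k + 1L
    }
    states[tr$edge[r, 2L]] <- s
    changes[r] <- k
  }
  tips <- states[seq_len(ntip)]
  names(tips) <- tr$tip.label
  list(tip_states = tips,
       node_states = states[(ntip + 1L):(ntip + tr$Nnode)],
       branch_changes = changes,
       tree = tr)
}
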