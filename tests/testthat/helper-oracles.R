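# Independent brute-force oracles.  These deliberately avoid the package's
# pruning/Fitch/quartet code paths: transition probabilities come from
# Matrix::expm, likelihoods from exhaustive enumeration over internal-node
# states, parsimony from exhaustive minimisation, induced quartets from
# ape::keep.tip.

## exhaustive log-likelihood by summing over all internal-state assignments
brute_loglik <- function(tree, aln, model) {
  Q <- build_rate_matrix(model)
  rc <- flyphy:::.rate_classes(model)
  sets <- flyphy:::.state_sets(model$alphabet)
  nst <- length(model$alphabet$states)
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nn <- ntip + tr$Nnode
  ints <- (ntip + 1L):nn
  mat <- aln$seq[tr$tip.label, , drop = FALSE]
  Plist <- lapply(rc$rates, function(r)
    lapply(seq_len(nrow(tr$edge)), function(e)
      as.matrix(Matrix::expm(Q * tr$edge.length[e] * r))))
  combos <- as.matrix(expand.grid(rep(list(seq_len(nst)), length(ints))))
  site_ll <- numeric(ncol(mat))
  for (site in seq_len(ncol(mat))) {
    tipsets <- lapply(seq_len(ntip), function(i) sets[[mat[i, site]]])
    lik <- 0
    for (cat in seq_along(rc$rates)) {
      P <- Plist[[cat]]
      tot <- 0
      for (ci in seq_len(nrow(combos))) {
        s <- integer(nn)
        s[ints] <- combos[ci, ]
        ## sum over compatible tip states
        p_root <- model$freqs[s[ntip + 1L]]
        p <- p_root
        for (e in seq_len(nrow(tr$edge))) {
          par <- tr$edge[e, 1L]
          ch <- tr$edge[e, 2L]
          if (ch <= ntip) {
            p <- p * sum(P[[e]][s[par], tipsets[[ch]]])
          } else {
            p <- p * P[[e]][s[par], s[ch]]
          }
        }
        tot <- tot + p
      }
      lik <- lik + rc$weights[cat] * tot
    }
    site_ll[site] <- log(lik)
  }
  list(loglik = sum(site_ll), site_loglik = site_ll)
}

## exhaustive minimum-change count (Fitch oracle)
brute_parsimony <- function(tree, aln) {
  sets <- flyphy:::.state_sets(aln$alphabet)
  nst <- length(aln$alphabet$states)
  tr <- ape::reorder.phylo(ape::root(ape::unroot(tree),
                                     outgroup = tree$tip.label[1L],
                                     resolve.root = TRUE), "postorder")
  ntip <- length(tr$tip.label)
  nn <- ntip + tr$Nnode
  ints <- (ntip + 1L):nn
  mat <- aln$seq[tr$tip.label, , drop = FALSE]
  combos <- as.matrix(expand.grid(rep(list(seq_len(nst)), length(ints))))
  total <- 0L
  for (site in seq_len(ncol(mat))) {
    tipsets <- lapply(seq_len(ntip), function(i) sets[[mat[i, site]]])
    best <- Inf
    for (ci in seq_len(nrow(combos))) {
      s <- integer(nn)
      s[ints] <- combos[ci, ]
      cost <- 0L
      for (e in seq_len(nrow(tr$edge))) {
        par <- s[tr$edge[e, 1L]]
        ch <- tr$edge[e, 2L]
        if (ch <= ntip) {
          if (!(par %in% tipsets[[ch]])) cost <- cost + 1L
        } else if (s[ch] != par) cost <- cost + 1L
      }
      if (cost < best) best <- cost
    }
    total <- total + best
  }
  total
}

## induced quartet topology id via keep.tip: 1 = q1q2|q3q4 etc., 0 unresolved
oracle_quartet_topology <- function(tree, quad) {
  quad <- sort(quad)
  sub <- ape::unroot(ape::keep.tip(tree, quad))
  refs <- lapply(list(c(2L, 3L, 4L), c(3L, 2L, 4L), c(4L, 2L, 3L)),
                 function(o) ape::read.tree(text = sprintf(
                   "((%s,%s),(%s,%s));", quad[1L], quad[o[1L]],
                   quad[o[2L]], quad[o[3L]])))
  for (k in 1:3)
    if (phangorn::RF.dist(sub, refs[[k]]) == 0) return(k)
  0L
}

## brute-force quartet agreement score
oracle_quartet_score <- function(species_tree, gene_trees) {
  taxa <- species_tree$tip.label
  score <- 0L
  for (g in gene_trees) {
    shared <- intersect(taxa, g$tip.label)
    if (length(shared) < 4L) next
    quads <- utils::combn(sort(shared), 4L)
    for (q in seq_len(ncol(quads))) {
      ts <- oracle_quartet_topology(species_tree, quads[, q])
      tg <- oracle_quartet_topology(g, quads[, q])
      if (tg > 0L && tg == ts) score <- score + 1L
    }
  }
  score
}

## exhaustive Mk2 marginal probabilities (joint enumeration, Matrix::expm)
brute_mk2_marginals <- function(tree, states, q01, q10) {
  Q <- matrix(c(-q01, q01, q10, -q10), 2L, byrow = TRUE)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  P <- lapply(seq_len(nrow(tree$edge)), function(r)
    as.matrix(Matrix::expm(Q * tree$edge.length[r])))
  pi <- c(q10, q01) / (q01 + q10)
  ints <- (ntip + 1L):nn
  probs <- matrix(0, length(ints), 2L)
  combos <- as.matrix(expand.grid(rep(list(1:2), length(ints))))
  tipsets <- lapply(states[tree$tip.label], function(s)
    switch(s, "0" = 1L, "1" = 2L, "?" = 1:2))
  for (ci in seq_len(nrow(combos))) {
    s <- integer(nn)
    s[ints] <- combos[ci, ]
    p <- pi[s[ntip + 1L]]
    for (r in seq_len(nrow(tree$edge))) {
      par <- s[tree$edge[r, 1L]]
      ch <- tree$edge[r, 2L]
      if (ch <= ntip) {
        p <- p * sum(P[[r]][par, tipsets[[ch]]])
      } else {
        p <- p * P[[r]][par, s[ch]]
      }
    }
    for (k in seq_along(ints)) probs[k, s[ints[k]]] <-
        probs[k, s[ints[k]]] + p
  }
  probs / rowSums(probs)
}

## random alignment helper
random_aln <- function(taxa, n_sites, alphabet, seed) {
  set.seed(seed)
  m <- matrix(sample(alphabet$states, length(taxa) * n_sites, TRUE),
              length(taxa), n_sites)
  rownames(m) <- taxa
  phy_alignment(m, alphabet)
}
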