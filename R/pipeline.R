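# Supermatrix assembly utilities, matrix diagnostics, and the end-to-end
# orchestration of the hypothesis-testing analysis on synthetic data.

#' Concatenate gene alignments into a supermatrix
#'
#' Genes are concatenated in name order of the input list; the taxon set is
#' the union over genes, and taxa absent from a gene are padded with the
#' alphabet's fully ambiguous symbol.  Partition intervals are recorded.
#'
#' @param gene_alignments named list of [phy_alignment()]s on a common
#'   alphabet.
#' @return list with `alignment` and `partitions` (a [partition_map()]).
#' @export
concat_supermatrix <- function(gene_alignments) {
  .stop_if(length(gene_alignments) == 0L, "no gene alignments")
  nms <- names(gene_alignments)
  .stop_if(is.null(nms) || anyDuplicated(nms) > 0L,
           "duplicate gene name")
  alphabet <- gene_alignments[[1L]]$alphabet
  for (g in gene_alignments)
    .stop_if(g$alphabet$name != alphabet$name, "mixed alphabets")
  taxa <- sort(unique(unlist(lapply(gene_alignments, aln_taxa))))
  gap <- .missing_symbol(alphabet)
  blocks <- lapply(gene_alignments, function(g) {
    m <- matrix(gap, length(taxa), aln_nsites(g),
                dimnames = list(taxa, NULL))
    m[aln_taxa(g), ] <- g$seq
    m
  })
  list(alignment = phy_alignment(do.call(cbind, blocks), alphabet),
       partitions = partition_map(nms,
                                  vapply(gene_alignments, aln_nsites,
                                         integer(1L))))
}

#' Split a supermatrix back into gene alignments
#'
#' Inverse of [concat_supermatrix()] up to the padding of missing taxa.
#'
#' @param aln a [phy_alignment()].
#' @param parts a [partition_map()] covering it.
#' @return named list of per-gene [phy_alignment()]s.
#' @export
split_supermatrix <- function(aln, parts) {
  .check_partitions(parts, aln_nsites(aln))
  out <- lapply(seq_len(nrow(parts)), function(i)
    .aln_subset(aln, sites = (parts$start[i] + 1L):parts$end[i]))
  names(out) <- parts$gene
  out
}

#' Alignment completeness (Ca)
#'
#' Fraction of matrix cells holding a fully specified character (a state of
#' the alphabet, not a gap or ambiguity code).
#'
#' @param aln a [phy_alignment()].
#' @return a number in `[0, 1]`.
#' @export
completeness_ca <- function(aln) {
  .stop_if(aln_nsites(aln) == 0L || nrow(aln$seq) == 0L, "empty matrix")
  mean(aln$seq %in% aln$alphabet$states)
}

#' Codon-position subsets
#'
#' Extracts 2nd (`NT2`) or 1st+2nd (`NT12`) codon positions from a
#' nucleotide supermatrix, assuming the reading frame starts at each
#' gene's first column; the partition map is rescaled accordingly.
#'
#' @param aln nucleotide [phy_alignment()].
#' @param parts [partition_map()]; every gene length must be divisible by 3.
#' @param which `"NT2"` or `"NT12"`.
#' @return list with `alignment` and `partitions`.
#' @export
codon_subsets <- function(aln, parts, which = c("NT2", "NT12")) {
  which <- match.arg(which)
  .check_partitions(parts, aln_nsites(aln))
  .stop_if(aln$alphabet$name != "nt", "codon positions need nucleotides")
  len <- parts$end - parts$start
  bad <- parts$gene[len %% 3L != 0L]
  .stop_if(length(bad) > 0L, "partition length not divisible by 3: ",
           paste(bad, collapse = ", "))
  keep_mod <- if (which == "NT2") 1L else c(0L, 1L)
  cols <- integer(0)
  for (i in seq_len(nrow(parts))) {
    idx <- parts$start[i]:(parts$end[i] - 1L)        # 0-based
    cols <- c(cols, idx[(idx - parts$start[i]) %% 3L %in% keep_mod])
  }
  sub <- .aln_subset(aln, sites = cols + 1L)
  list(alignment = sub,
       partitions = partition_map(parts$gene,
                                  len / 3L * length(keep_mod)))
}

#' Mask terminal gaps
#'
#' Replaces maximal leading and trailing runs of `-` in each sequence with
#' the alphabet's ambiguity symbol (`N` for nucleotides, `X` for amino
#' acids); internal gaps are untouched.  Under the likelihood engine both
#' codes are total ambiguity, so masking never changes a likelihood -- it
#' only makes the conventional distinction between "no data off the ends"
#' and aligned gaps explicit.
#'
#' @param aln nucleotide or amino-acid [phy_alignment()].
#' @return the masked [phy_alignment()].
#' @export
mask_terminal_gaps <- function(aln) {
  .stop_if(!aln$alphabet$name %in% c("nt", "aa"),
           "terminal-gap masking applies to nucleotide or amino-acid data")
  sym <- .missing_symbol(aln$alphabet)
  m <- aln$seq
  for (i in seq_len(nrow(m))) {
    row <- m[i, ]
    nongap <- which(row != "-")
    if (length(nongap) == 0L) {
      m[i, ] <- sym
      next
    }
    if (nongap[1L] > 1L) m[i, seq_len(nongap[1L] - 1L)] <- sym
    last <- nongap[length(nongap)]
    if (last < length(row)) m[i, (last + 1L):length(row)] <- sym
  }
  phy_alignment(m, aln$alphabet)
}

#' Run configuration
#'
#' Builds and validates the configuration driving [run_analysis()].  Every
#' stochastic stage derives its RNG stream from the single top-level seed,
#' which must be given explicitly.  The configuration round-trips through
#' YAML losslessly.
#'
#' @param config named list (typically from [read_run_config()]).
#' @return validated list of class `run_config`.
#' @export
run_config <- function(config) {
  .stop_if(!is.list(config), "config must be a list")
  .stop_if(is.null(config$seed), "config is missing a seed")
  .stop_if(!.is_count(config$seed + 1), "seed must be an integer")
  defaults <- list(
    supermatrix = list(backbone = "T1", n_genes = 40L, mean_length = 60L,
                       rate_sd = 0.4, completeness = 1.0,
                       internal_bl = 0.05, terminal_bl = 0.2,
                       model = list(type = "poisson", alpha = 0.8,
                                    ncat = 4L)),
    delta_pl = list(enabled = TRUE),
    fclm = list(enabled = TRUE, max_quartets = 10000L),
    au_test = list(enabled = TRUE, replicates = 1000L),
    mp_jackknife = list(enabled = FALSE, replicates = 100L,
                        deletion = 0.36),
    quartet_tree = list(enabled = FALSE, n_loci = 100L, n_taxa = 7L,
                        coalescent_scale = 2),
    asr = list(enabled = FALSE, generations = 5000L, burnin = 1000L,
               thin = 10L))
  for (sec in names(defaults)) {
    got <- config[[sec]] %||% list()
    merged <- utils::modifyList(defaults[[sec]], got)
    config[[sec]] <- merged
  }
  structure(config, class = "run_config")
}

#' @rdname run_config
#' @param file YAML path.
#' @export
read_run_config <- function(file) run_config(yaml::read_yaml(file))

#' @rdname run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, file) {
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}

.config_model <- function(spec) {
  switch(spec$type,
         poisson = model_poisson(alpha = spec$alpha, ncat = spec$ncat),
         lg = model_lg(alpha = spec$alpha, ncat = spec$ncat),
         jc = model_jc(alpha = spec$alpha, ncat = spec$ncat),
         stop("unknown model type: ", spec$type, call. = FALSE))
}

#' Run the full analysis
#'
#' Orchestrates, on a synthetic supermatrix simulated from a backbone
#' fixture: branch-length optimisation of T1/T2/T3, the per-partition
#' log-likelihood table and favoring counts, both paraphyly-aware FcLM
#' variants, the KH/SH/AU report, and (optionally) parsimony jackknife,
#' the exact quartet species tree from coalescent gene trees, and
#' ancestral-state reconstruction of metallic coloration.  All outputs are
#' written as TSV/Newick under `out_dir` together with a provenance log
#' (config hash, seeds, package version); two runs with equal
#' configurations are byte-identical.
#'
#' @param config a [run_config()] (or plain list passed through it).
#' @param out_dir output directory, created if needed.
#' @return named list of in-memory results, invisibly.
#' @export
run_analysis <- function(config, out_dir) {
  config <- run_config(unclass(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_file <- file.path(out_dir, "config.yaml")
  write_run_config(config, cfg_file)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  seed <- as.integer(config$seed)
  results <- list()
  prov <- c(sprintf("flyphy %s", as.character(utils::packageVersion("flyphy"))),
            sprintf("config_hash %s", cfg_hash),
            sprintf("seed %d", seed))
  stage <- function(name, expr) {
    message("[", name, "] running")
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  sm_cfg <- config$supermatrix
  model <- .config_model(sm_cfg$model)
  fixture <- backbone_fixture(sm_cfg$backbone,
                              internal_bl = sm_cfg$internal_bl,
                              terminal_bl = sm_cfg$terminal_bl)
  sm <- stage("supermatrix", {
    specs <- sample_gene_specs(sm_cfg$n_genes, fixture$tree$tip.label,
                               mean_length = sm_cfg$mean_length,
                               rate_sd = sm_cfg$rate_sd,
                               completeness = sm_cfg$completeness,
                               seed = .derive_seed(seed, 1L))
    simulate_supermatrix(fixture$tree, specs, model,
                         .derive_seed(seed, 2L))
  })
  write_fasta(sm$alignment, file.path(out_dir, "supermatrix.fasta"))
  write_partitions(sm$partitions, file.path(out_dir, "partitions.txt"))
  prov <- c(prov, sprintf("completeness_ca %.6f",
                          completeness_ca(sm$alignment)))
  results$supermatrix <- sm

  trees <- lapply(c(T1 = "T1", T2 = "T2", T3 = "T3"), function(h)
    backbone_fixture(h, internal_bl = sm_cfg$internal_bl,
                     terminal_bl = sm_cfg$terminal_bl)$tree)

  if (isTRUE(config$delta_pl$enabled)) {
    dpl <- stage("delta_pl",
                 per_partition_delta_pl(sm$alignment, sm$partitions, trees,
                                        model))
    .write_tsv(as.data.frame(dpl), file.path(out_dir, "delta_pl.tsv"))
    for (pair in list(c("T1", "T2"), c("T1", "T3"))) {
      cf <- count_favoring(dpl, pair)
      prov <- c(prov, sprintf("favoring_%s_%s %d %d %d", pair[1L], pair[2L],
                              cf[1L], cf[2L], cf[3L]))
    }
    results$delta_pl <- dpl
  }

  if (isTRUE(config$fclm$enabled)) {
    g <- fixture$groups
    fv <- stage("fclm",
                fclm_paraphyly_variants(sm$alignment, g$group1, g$group2a,
                                        g$group2b, g$group3, g$outgroup,
                                        model,
                                        max_quartets = config$fclm$max_quartets,
                                        seed = .derive_seed(seed, 3L)))
    write_fclm_tsv(fv$without_2b, file.path(out_dir, "fclm_without2b.tsv"))
    write_fclm_tsv(fv$without_2a, file.path(out_dir, "fclm_without2a.tsv"))
    results$fclm <- fv
  }

  if (isTRUE(config$au_test$enabled)) {
    .stop_if(is.null(results$delta_pl),
             "au_test needs the delta_pl stage enabled")
    report <- stage("au_test",
                    topology_test_suite(attr(results$delta_pl, "site_ll"),
                                        replicates = config$au_test$replicates,
                                        seed = .derive_seed(seed, 4L)))
    .write_tsv(as.data.frame(report), file.path(out_dir, "test_report.tsv"))
    results$topology_tests <- report
  }

  if (isTRUE(config$mp_jackknife$enabled)) {
    mp <- stage("mp_jackknife", {
      rec <- if (sm$alignment$alphabet$name == "aa")
        dayhoff6_recode(sm$alignment) else sm$alignment
      jackknife_support(rec, deletion = config$mp_jackknife$deletion,
                        replicates = config$mp_jackknife$replicates,
                        seed = .derive_seed(seed, 5L))
    })
    .write_tsv(as.data.frame(mp), file.path(out_dir, "mp_support.tsv"))
    write_newick(attr(mp, "tree"), file.path(out_dir, "mp_tree.nwk"))
    results$mp_jackknife <- mp
  }

  if (isTRUE(config$quartet_tree$enabled)) {
    qt <- stage("quartet_tree", {
      n_taxa <- config$quartet_tree$n_taxa
      sp <- ape::keep.tip(fixture$tree, fixture$tree$tip.label[
        seq_len(min(n_taxa, length(fixture$tree$tip.label)))])
      sp$edge.length <- sp$edge.length /
        mean(sp$edge.length) * config$quartet_tree$coalescent_scale
      gts <- simulate_gene_trees_msc(sp, config$quartet_tree$n_loci,
                                     .derive_seed(seed, 6L))
      est <- exact_quartet_species_tree(gts, sp$tip.label)
      list(species_tree = sp, estimate = est)
    })
    write_newick(qt$estimate$trees[[1L]],
                 file.path(out_dir, "species_tree.nwk"))
    prov <- c(prov, sprintf("quartet_score %d", qt$estimate$score))
    results$quartet_tree <- qt
  }

  if (isTRUE(config$asr$enabled)) {
    asr <- stage("asr", {
      trait <- if (is.null(config$asr$trait))
        read_trait_tsv(system.file("extdata", "metallic_trait.tsv",
                                   package = "flyphy", mustWork = TRUE))
      else binary_trait(unlist(config$asr$trait))
      tr <- fixture$tree
      tr$edge.length <- rep(1, nrow(tr$edge))  # cladogram convention
      fit <- fit_mk2(tr, trait)
      bb <- bbm_asr(tr, trait, generations = config$asr$generations,
                    burnin = config$asr$burnin, thin = config$asr$thin,
                    seed = .derive_seed(seed, 7L))
      orig <- count_origins(tr, trait, bb)
      list(fit = fit, bbm = bb, origins = orig)
    })
    write_asr_tsv(asr$bbm, file.path(out_dir, "asr_probs.tsv"))
    prov <- c(prov, sprintf("asr_gains %d losses %d",
                            asr$origins$n_gains, asr$origins$n_losses))
    results$asr <- asr
  }

  writeLines(prov, file.path(out_dir, "provenance.txt"))
  invisible(results)
}
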