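Package: flyphy
Title: Phylogenomic Hypothesis Testing for Blowfly Monophyly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Likelihood-based phylogenomic hypothesis testing at the
    blowfly (Calliphoridae) subfamily level: supermatrix assembly and
    diagnostics, a pruning-algorithm likelihood engine with per-site
    log-likelihoods over nucleotide, amino-acid, Dayhoff-recoded and
    binary alphabets, per-partition log-likelihood comparison of
    competing placements of Chrysomyinae, paraphyly-aware four-cluster
    likelihood mapping, RELL-based Kishino-Hasegawa,
    Shimodaira-Hasegawa and approximately unbiased topology tests,
    Fitch parsimony with jackknife support, exact quartet-score species
    trees from gene trees, and two-state Markov ancestral-state
    reconstruction of adult metallic coloration.  Ships seeded
    generators (supermatrices with per-gene rates and missing data,
    multispecies-coalescent gene trees, binary traits) so the full
    analysis runs end-to-end on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phangorn,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
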