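---
title: "Methods: likelihood-based tests of blowfly subfamily placement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: likelihood-based tests of blowfly subfamily placement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flyphy)
```

## The scientific problem

Blowflies (Calliphoridae) have long resisted a monophyletic definition.
Phylogenomic supermatrices resolve most of the subfamily backbone, but the
placement of Chrysomyinae is unstable across data sets.  Three rival
hypotheses recur:

* **T1** — Chrysomyinae + Phumosiinae (*group 1*) are sister to all
  remaining calliphorids;
* **T2** — Chrysomyinae attach to Luciliinae + the Calliphorinae group
  (*group 3*);
* **T3** — Chrysomyinae attach to Rhiniidae + Bengaliinae (*group 2b*).

`flyphy` packages the statistical machinery needed to weigh these
hypotheses against each other on a partitioned supermatrix — per-partition
log-likelihood differences, four-cluster likelihood mapping (FcLM), and
the RELL-based KH/SH/AU tests — together with parsimony and
quartet-coalescent cross-checks and an ancestral-state analysis of adult
metallic coloration.  Because the original transcriptomic supermatrix
(thousands of genes, over a million aligned residues) is far beyond desk
scale, the package ships seeded generators that emulate its statistical
structure; all claims the test suite makes are claims about this synthetic
regime.

## The likelihood engine

All likelihood-based stages share one engine: Felsenstein's pruning
algorithm over a reversible continuous-time Markov chain with discrete
gamma rate classes.  Models are parameterised GTR-style by symmetric
exchangeabilities and equilibrium frequencies; the generator is normalised
to one expected substitution per unit branch length (trait models opt
out, because their rates live on the tree's own time scale).  The engine
factorises each transition matrix through the symmetric eigendecomposition
of the generator, which serves three purposes: a stable matrix
exponential, the ergodic limit for free, and a representation in which the
likelihood along a *single* branch can be re-evaluated in O(states ×
patterns) during branch-length optimisation.

Numerical choices that matter:

* **Site patterns** are compressed once per (tree, alignment) pair;
  identical columns share all computation.
* **Underflow** is handled by per-node, per-rate-class rescaling of
  partial likelihoods with the log scalers accumulated separately, so
  matrices well beyond 10^5 sites stay in range.
* **Ambiguity**: every symbol outside the core alphabet maps to the subset
  of states it is compatible with; gaps, `N` and `X` all contribute a
  partial likelihood of 1 for every state.  This matches the terminal-gap
  recoding convention used for transcriptome supermatrices and makes
  `mask_terminal_gaps()` a likelihood-neutral relabelling (a property the
  tests assert).
* **Branch-length optimisation** is cyclic Brent per branch (tolerance
  `1e-6`, at most 20 sweeps by default).  Each sweep recomputes the
  postorder partials, then walks the tree in preorder keeping "flank"
  partials for the branch being optimised; the returned tree never has a
  lower log-likelihood than the input.  Gamma uses 4 equal-probability
  categories with bin-mean rates, the field's default.
* **Rate classes for quartets**: FcLM optimises branch lengths per quartet
  with a looser tolerance (`1e-3`, 3 sweeps).  Quartet weights are a
  softmax over log-likelihood differences that are typically tens to
  hundreds of units, so sub-0.001 convergence buys nothing; the choice is
  exposed as `bl_tol`/`bl_cycles`.

Model families shipped: JC/GTR for nucleotides, Poisson and LG for amino
acids (LG taken from phangorn's bundled tables), an equal-exchangeability
six-state model for Dayhoff-recoded data, and the two-state gain/loss
model for traits.  Model selection is deliberately out of scope: the
original per-gene best-fit models are unknowable here, so every analysis
runs under a single configured model and says so.

## Per-partition log-likelihoods and gene counts

For gene *i* and trees *A*, *B*, the statistic is
\[
\Delta pL_i = pL_i(A) - pL_i(B),
\]
where the per-gene values are sums of per-site log-likelihoods inside the
gene's partition.  Branch lengths are optimised **once per tree on the
full supermatrix**, then held fixed for per-gene scoring; this mirrors
scoring each locus against the full-data trees and makes the table exactly
additive (the column sums reproduce each tree's total, a tested
invariant).  `count_favoring()` tallies the signs; differences below
`1e-9` are reported as an explicit tie category rather than allocated —
with thousands of genes, a small unallocated remainder is expected and
should be visible, not hidden.

## Four-cluster likelihood mapping with a paraphyletic cluster

FcLM draws quartets one taxon per group, scores the three resolved quartet
topologies by maximum likelihood, and maps the softmax weight triple onto
the 2-simplex.  The headline "basin" percentages are argmax counts, which
are independent of any region geometry; a 7-region refinement (three
corners at \(w_i \ge 2/3\), three edges when the smallest weight is
\(\le 1/6\), a centre otherwise, ties resolved toward the centre) is also
reported because published percentages are sometimes corner rather than
basin tallies.

The group of interest here ("group 2") is paraphyletic, so plain FcLM does
not apply.  Following the modified design, the group is split into 2a and
2b and the mapping run twice: once with the 2b taxa pruned from the
alignment, once with 2a pruned.  Pruned runs keep only the four active
clusters, since quartets are drawn solely from group members.  In both
variants the basin pairing group 1 with the outgroup corresponds to
"group 1 sister to all remaining calliphorids", i.e. the T1 arrangement.

One design point deserves a note.  The acceptance suite checks that on
data generated under the *T3 grouping* the 2b-retaining variant flips its
plurality basin to group 1 + group 2b.  That check simulates on the
group-level arrangement (the whole of group 1 sister to group 2b).  Under
the 11-taxon T3 fixture — where only Chrysomyinae moves — the variant's
twelve quartets split 6:6 between two basins by construction (Chrysomyinae
quartets support group 1 + 2b, Phumosiinae quartets support group 1
basal), so a plurality there would be a coin toss, not a signal; the
group-level arrangement is the regime in which the flip is a well-defined
prediction.

## RELL resampling and the KH / SH / AU tests

All three tests consume the per-site log-likelihood matrix and never
re-optimise anything (RELL).  A replicate at scale *r* draws
`round(r * n)` sites with replacement — implemented as one multinomial
weight vector and a matrix product.

* **KH** (one-sided): each tree against the ML tree, with the replicate
  difference distribution centred at zero; the best tree is assigned
  *p* = 1 by construction.
* **SH**: the joint null centres each tree's replicate totals at that
  tree's mean and compares the observed deficit against the centred
  maximum across trees — simultaneously valid for all trees.
* **AU**: bootstrap proportions are computed at ten scales
  (0.5–1.4), probit-transformed, and fitted by weighted least squares to
  \(z(r) = d\sqrt r + c/\sqrt r\); then \(p = 1 - \Phi(d - c)\).
  Proportions are clamped to \([1/(2B), 1 - 1/(2B)]\) before the
  transform.  A tree that is never best at any scale is reported at
  \(p = 1/(2B)\) with a `never_best` flag rather than a hard zero.
  Replicates default to 1000 (configurable; the original analysis used
  10,000).

Degenerate ties (identical per-site rows) are flagged and give
*p*-KH = *p*-SH = 1 and *p*-AU ≈ 0.5, which is what a tie should look
like under a symmetric null.

## Parsimony and the quartet species tree

The MP stand-in scores Dayhoff-recoded matrices (six biochemical groups,
reducing saturation and compositional artifacts) with a bitmask Fitch
pass, ambiguity sets used directly as tip state sets.  Search is greedy
NNI hill-climbing with seeded tie-breaking and multi-start; the driven
searches of specialised MP software are deliberately replaced, and
adequacy is claimed only at the ≤ 11-taxon scale the tests exercise.
Jackknife support deletes each site independently with probability 0.36
per replicate (the convention associated with parsimony jackknifing) and
reports, for each split of the best full-data tree, the percentage of
replicate trees containing it.

The coalescent stand-in scores candidate species trees by their quartet
agreement with the gene trees and, at the subfamily-exemplar scale
(4–9 taxa), simply enumerates all `(2n-5)!!` topologies — an exact
replacement for heuristic quartet-score search.  Gene trees may miss taxa
(they contribute fewer quadruples) and polytomies contribute no resolved
quartets.  Gene-set resampling is used for support values, with a split
credited only when every co-optimal replicate tree contains it; the
resampling scheme is an assumption and is flagged as such.

## Ancestral state of adult metallic coloration

Metallic coloration is coded present/absent (partially metallic taxa count
as present; no multistate coding is attempted).  The model is the
two-state Markov chain with gain rate `q01` and loss rate `q10`;
`fit_mk2()` maximises the pruning likelihood over both rates (bounds
`1e-6`–`1e3`), with an `equal_rates` option realising the "equal weight"
character treatment.  `marginal_asr()` computes exact per-node marginal
probabilities by the up-down algorithm with the root at the stationary
distribution of the rates (a flat-root option exists; stationarity is the
standard default when a tool's own prior is undocumented).  `bbm_asr()`
wraps the same marginals in a Metropolis–Hastings sampler over the rates
— independent exponential(mean 1) priors, Gaussian proposals of SD 0.3 on
the log scale — and averages the marginals over the posterior, reporting
acceptance rate and effective sample sizes.  The analysis tree is a
cladogram (all branch lengths 1), matching an analysis run on a topology
without published lengths; real-valued trees are accepted.

`count_origins()` turns probabilities into a state assignment (argmax by
default, ties following the parent, root ties resolved to absent) and
counts 0→1 edges as gains, 1→0 edges as losses.  Unknown tips inherit
their parent's assignment so they never create spurious transitions.  On
the bundled subfamily-exemplar coding of the metallic trait with the
published assignment — metallic Chrysomyinae + Phumosiinae, metallic clade
(Rhiniidae–Bengaliinae–Luciliinae–Calliphorinae–Toxotarsinae), metallic
Ameniinae, everything above them non-metallic — the count is three
independent gains, the figure the analysis is known for.

## The synthetic-data generators

The generators define the study conditions for every test:

* `simulate_supermatrix()` emulates a transcriptomic supermatrix: genes
  with log-normal length variation (defaults sized to a 2221-gene,
  ~0.71-complete amino-acid matrix: mean length 536, completeness 0.709),
  log-normal per-gene rate multipliers (SD 0.4 on the log scale, mean 1),
  and taxon-wise missingness in whole gene blocks — the way transcriptome
  matrices actually lose data.
* `backbone_fixture()` fixes the three 11-exemplar hypothesis trees
  (internal branches 0.05, terminals 0.2 substitutions/site — realistic
  signal for a calyptrate backbone and configurable for power studies).
* `simulate_gene_trees_msc()` runs the standard multispecies coalescent
  (exponential waiting times at rate \(k(k-1)/2\) within branches measured
  in coalescent units); its rooted-triple concordance matches
  \(1 - \tfrac23 e^{-t}\), a tested closed form.
* `simulate_binary_trait()` is event-based (Gillespie), so it returns the
  realised number of changes per branch along with true node states —
  which lets tests check Poisson change counts and use the Fitch score as
  a lower bound on true changes.

What the generators do **not** emulate: indels and alignment error,
assembly/orthology artifacts, compositional heterogeneity across lineages,
and codon structure within genes.  Passing tests therefore demonstrate
correctness of the statistical machinery under the model class it assumes,
not robustness to the violations real data bring.

## Problem sizes used by the test suite

The acceptance suite runs the full pipeline at deliberately desk-sized
conditions chosen once: 200 genes × 300 amino acids on the T1 backbone for
the gene-count and FcLM checks; 50 seeded replicates at 500 RELL
replicates × 10 scales for AU calibration (six taxa, 1000 nucleotide
sites; internal branches 0.05 for the moderate-signal regime, 0.15 for
strong signal); 20 seeded runs of 200 coalescent gene trees on a six-taxon
species tree; 10,000 loci per point for the concordance curve; and a
bundled demonstration configuration that exercises every stage end to end
twice to prove byte-identical reruns.  The MCMC demonstrations use short
chains (a few thousand generations) sized for convergence on the
64-tip fixtures they run on, monitored by acceptance rate, effective
sample size and a four-chain potential-scale-reduction check.

## Known limitations

* No tree search over topology space for the likelihood stages:
  hypotheses are supplied, not discovered (constrained searches in the
  original workflow are replaced by fixed constraint-satisfying trees).
* One substitution model per run; no per-gene models, no model selection.
* The exact quartet species tree is capped at nine taxa by design.
* Greedy NNI parsimony search can stall in local optima on random starts;
  multi-start mitigates but does not eliminate this, which is why the
  exhaustive check pins it only at the six-taxon scale.
* AU *p*-values inherit Monte-Carlo error of order \(1/\sqrt B\); with the
  default \(B = 1000\) the calibration tests allow for it explicitly.
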