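---
title: "Network-shift biomarker analysis for longitudinal microbiome studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-shift biomarker analysis for longitudinal microbiome studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem this package addresses

Chronic stressors reshape gut microbial communities in ways that simple
per-taxon abundance tests often miss: taxa change *who they co-occur with*
before (or instead of) changing how abundant they are. netshiftr implements
a network-based differential-abundance workflow for longitudinal two-arm
(control vs stress) 16S cohorts: genus-level count tables are filtered and
rarefied, co-occurrence networks are inferred per condition with SparCC,
modules are detected by topological-overlap clustering, and each genus is
scored by how much it restructures the module architecture between the two
condition networks. Significance comes from a label-permutation null with
Benjamini-Hochberg FDR control, and candidate biomarker panels are
evaluated with cross-validated ROC.

Because the workflow is meant to be testable end to end without access to
any particular cohort, the package ships a synthetic community generator
with planted, known structure. All tests and the acceptance script run
against it.

## The synthetic community generator

`simulate_counts()` draws latent absolute abundances from a multivariate
log-normal whose correlation matrix is block structured: taxa inside a
planted module share a common basis correlation (default 0.7), taxa in
different modules are uncorrelated. Observed counts are multinomial draws
from the normalized latent composition at a per-sample depth drawn from a
lognormal-rounded law (mean 45,000 reads, CV 0.3), so each row sum equals
its drawn depth exactly. A log-normal basis was chosen over a
Dirichlet-multinomial because SparCC itself models log-basis correlations;
parameter-recovery tests are then well posed.

Defaults describe the kind of cohort the pipeline targets: 150 genera,
two arms of 30 samples at each of three timepoints, four modules of sizes
25/20/15/10, and eight driver genera. In the stress arm a driver's mean is
shifted by a log2 fold change of 1.5 and, with `driver_rewire = TRUE`, its
correlation row moves to the next module — the network-level signal the
scoring stage is designed to detect. Sex is generated as a pure label with
zero effect, providing a built-in PERMANOVA null. Within-taxon latent
log-SD is 1.0, a deliberately noisy but realistic choice for genus-level
16S data; note that it caps the achievable single-feature ROC AUC of an
abundance shift (a 4-fold shift gives a population AUC of about
`pnorm(2 * log(2) / sqrt(2))` ≈ 0.84).

`simulate_resilience_trajectory()` emulates an acute stressor with
recovery: the driver effect is applied in full at the perturbed timepoint
and scaled by `1 - recovery_fraction` afterwards. The multiplier scales
*both* the mean shift and the correlation rewiring (as a convex
combination of the two PSD basis matrices, which stays PSD); without the
latter, an "acute" perturbation would leave no network signal for the
scoring stage to localize.

What the generator does **not** emulate: phylogenetic signal, taxon-taxon
interactions beyond block correlation, overdispersion beyond the
log-normal, repeated measures on the same animals, or batch effects
between timepoints. Passing tests therefore demonstrate the pipeline's
internal statistical validity, not performance on any real cohort.

## Filters, rarefaction, diversity

Filters run in the order singletons → low abundance → rarefaction. The
low-abundance rule retains a taxon iff its total count exceeds (strictly)
a fraction — default 0.0001% — of the pooled read total across all
samples; the threshold is global, not per sample, because it describes a
share of the total abundance. Rarefaction subsamples each sample without
replacement (multivariate hypergeometric, via `vegan::rrarefy`) to a
common depth, 31,731 reads by default; shallower samples are dropped and
reported, never padded. With-replacement rarefaction was rejected because
it biases richness estimators.

Alpha diversity uses Shannon in natural-log units (configurable base),
Simpson as `1 - sum(p^2)`, and the bias-corrected Chao1 and ACE estimators
(integer counts required). Whittaker beta diversity is reported in the
turnover form `gamma / mean(alpha) - 1`, which is 0 when all samples share
one composition; a flag switches to the ratio form. PERMANOVA uses the
distance-based pseudo-F with a label-permutation null (999 permutations by
default) and the plus-one p-value convention, so p is never exactly 0; the
implementation is cross-checked against `vegan::adonis2` in the test
suite.

## SparCC networks and integration

`sparcc()` estimates basis correlations from compositions: per inner
iteration, fractions are drawn from a Dirichlet posterior (counts + 0.5),
the log-ratio variation matrix is formed, basis variances are solved under
the sparsity approximation, and the strongest pairs are iteratively
excluded (up to 10 rounds while the top |correlation| exceeds 0.1 — the
algorithm's published defaults, all exposed). The final adjacency is the
entrywise median over 20 iterations, clipped to [-1, 1]. Two
implementation notes: draws are generated in sorted taxon order so the
estimate is exactly equivariant under permutation of input columns, and a
pair is never excluded if that would leave a taxon with fewer than two
partners (keeps the linear system nonsingular). SparCC's sparsity
assumption matters in practice: with a large fraction of taxa in strong
blocks, between-block estimates acquire a visible negative bias. The
planted designs used in the tests keep correlated taxa a minority.

Per-timepoint networks of one condition are integrated by a weighted
edgewise mean. The weights are inverse-variance weights from the Fisher-z
sampling variance of a correlation, `1/(n_t - 3)` — a univariate (per
edge) weighting scheme; explicit weights can be supplied instead. With
equal weights the integration reduces to the arithmetic mean of the
adjacencies, which the tests assert. Topology metrics (degree, strength,
betweenness, closeness) are computed on the graph binarized at
|a_ij| ≥ 0.3 by default.

## Module detection and node statistics

Modules are detected WGCNA-style: signed soft adjacency
`((1 + a)/2)^6`, topological overlap similarity, average-linkage
clustering of the TOM dissimilarity, and a *static* tree cut with a
minimum module size of 5; unassigned nodes are labeled grey. A static cut
was preferred over the dynamic hybrid cut for determinism and fewer
tunables. The default cut height is 0.9: on TOM dissimilarities even a
clean planted block (10 taxa at basis correlation 0.8, soft power 6) sits
near 0.5 internal dissimilarity, so cuts far below ~0.9 shatter real
modules into grey dust; 0.9 is the conventional static-cut height for TOM
dendrograms.

Two node statistics accompany every partition. Connection strength is
`k_i = sum_{j != i} a_ij` — the verbal definition ("all other nodes")
takes precedence over summation-bound notation, so the self-term is
excluded. Module importance is within-module minus out-of-module
connectivity, `sum_{j in M, j != i} a_ij - sum_{j not in M} a_ij`; it
reduces to `+k_i` when all of a node's connections are internal and to
`-k_i` for a singleton module, identities the tests verify exactly against
brute-force summation.

## The module-shift (NMSS) score

The driving-force score quantifies how much each taxon contributes to the
transition between the condition networks A and B. The differential
module distance matrix D holds Jaccard distances between the member sets
of every A-module and every B-module; module pairs with D below 0.3 are
flagged as stable ("intersection") modules. For the per-node score we use
a node-anchored differential: for a node pair (i, j), ΔD_ij is the
distance between the modules housing them in A minus that distance in B —
for two modules of one partition the Jaccard distance degenerates to the
0/1 different-module indicator, so ΔD_ij ∈ {-1, 0, +1} marks pairs whose
co-membership changed. The raw score of node i is the difference of two
neighbor sums,

    raw(i) = sum_{j in N_A(i)} |a_ij^A| * ΔD_ij  -  sum_{l in N_B(i)} |a_il^B| * ΔD_il

where N_X(i) are i's supra-threshold neighbors in network X and each term
is weighted by the edge strength. The reported score is |raw| min-max
normalized to [0, 1]. Design rationale, in order of importance:

* **Node-level neighbor sets.** Under the generator's own conditions
  (between-module correlation 0) *module-level* adjacency is empty, which
  would make every neighbor sum empty and every score 0. Anchoring the
  sums on the node's graph neighbors preserves the equation's structure
  while keeping it informative; the sets of modules housing those
  neighbors are still exposed per node (`neighbors_A`, `neighbors_B`).
* **Edge-strength weighting.** A driver that genuinely rewires retains
  *attenuated* (~rho/2) correlations to both blocks when condition labels
  are permuted. Unweighted 0/1 discordance then gives null scores the
  same magnitude as observed ones and the permutation test has no power;
  weighting by |a_ij| separates pure-arm evidence (rho) from mixed-null
  evidence (~rho/2).
* **Self-transition null.** For A = B the two sums cancel term by term,
  so nmss(A→A) = 0 identically — asserted exactly in the tests.

Significance: condition labels are permuted over the pooled samples
(within timepoint strata in longitudinal mode) and the entire chain —
SparCC networks, partitions, scores — is recomputed per permutation. The
permutation statistic is |raw|, not the normalized score: min-max
normalization forces some taxon to 1.0 in every null draw, which deflates
power by construction. p-values use the plus-one convention and BH gives
q-values; the direction label comes from the sign of the mean
relative-abundance difference between arms. Permutation nulls run SparCC
in an economy mode (reduced inner iterations, recorded in the output
attributes); the default permutation count is 1000, and the bundled
analysis scripts use 200 with economy settings — problem sizes chosen so
a full run completes on a laptop in minutes.

One behavior worth understanding: when a driver leaves a module, the
remaining members' co-membership with that driver also changes, so
members of restructured modules receive nonzero (and sometimes
significant) scores. That is the method working as defined — module
restructuring is a property of the module, not only of the mover — but it
means "significant" is not synonymous with "planted driver";
`benchmark_against_truth()` reports precision against the planted set
explicitly.

## Evaluation

`netroc()` evaluates a biomarker panel with stratified k-fold
cross-validation: relative abundances of the panel taxa are features, a
logistic scorer (the simplest calibrated linear scorer; pluggable by
design) is fit per training split, and held-out scores are pooled into a
single trapezoidal ROC AUC. Per-fold AUCs and their mean are also
reported, since pooled and fold-averaged AUCs answer slightly different
questions. Features are relative abundances rather than counts so the
evaluation is invariant to rarefaction depth.

## Numerical and degenerate-input choices

* Basis variances from SparCC's linear system are floored at 1e-12 before
  the square root; correlations are clipped to [-1, 1].
* All alpha indices error on zero-sum samples; `relative_abundance`
  refuses all-zero rows rather than imputing.
* Missing cells in a count TSV are an error, never silently zero.
* PCoA fixes each axis' sign (first nonzero loading positive) so
  ordinations are reproducible; negative eigenvalues are reported, axes
  are limited to positive ones.
* ACE is defined as observed richness when a sample has no rare taxa.
* Average ranks break ties in rank-based statistics.
* A single global seed fans out to per-stage seeds through a counter-based
  mix (`derive_seed`), so any stage can be rerun independently yet
  reproducibly; all derived seeds stay below 2^31.

## Problem sizes used by the test suite

Deterministic identities run on 20-node random networks (100 of them for
the brute-force node-statistic check). SparCC parameter recovery uses 30
taxa at n = 500 (null) and n = 1000 (planted pair at 0.8). Driver-rank
recovery uses 40 taxa (two 8-taxon modules, basis correlation 0.8) at 60
samples per arm over 50 seeds. Calibration uses 200 null PERMANOVA
datasets, 20 null FDR datasets at 100 permutations, and 50 null netROC
draws. The acute-vs-chronic contrast uses 24 taxa, 30 samples per arm,
three timepoints and 150 permutations over 25 seeds, with the
significance-mode edge threshold at 0.45 — midway between the planted
within-module correlation (0.8) and its mixed-arm attenuation (~0.4) — and
economy SparCC settings applied identically to observed and null chains.

## Known limitations

* SparCC's sparsity assumption degrades when most taxa are strongly
  correlated; dense designs inflate between-module estimates.
* The label-permutation null re-estimates networks from mixed arms, which
  is conservative for weak rewiring signals near the edge threshold.
* Jaccard distance on member sets sees module *membership* shifts only;
  a module whose internal correlation strength changes without membership
  turnover is invisible to D (the distance function is pluggable for this
  reason).
* The longitudinal mode assumes a shared taxon universe across
  timepoints; taxa absent from a timepoint contribute zero-weight edges.
* netROC's logistic scorer is linear in relative abundances; strongly
  non-monotone abundance effects would need a different plug-in scorer.
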