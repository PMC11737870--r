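---
title: "Methods: dissecting trained-immunity transcriptomics with trainomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dissecting trained-immunity transcriptomics with trainomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

Trained immunity is the antigen-agnostic functional memory innate immune
cells acquire after a priming exposure such as BCG. Transcriptomically it
shows up in two ways: a condition-restricted gene program (STAT1-driven
interferon-response genes such as *Gbp2*, *Cxcl9*, *Ly6a*, *Irg1*) in
specific myeloid subsets of a single-cell experiment, and a time-resolved
bulk signature whose induction kinetics — early-transient, sustained, or
delayed — carry the biology. `trainomics` implements the downstream
analyses for both layers: MARS-seq-style UMI count preprocessing and
clustering for the single-cell layer, and an integral-difference statistic
over averaged log2 trajectories for the bulk kinetics layer, together with
the t-test/ANOVA differential-expression and over-representation machinery
that surrounds them.

Everything operates on plain matrices with genes as rows and
cells/samples as columns; that orientation is enforced everywhere.

# Single-cell preprocessing

The order of operations is fixed: cell QC, then gene filtering, then size
factors, then normalization, then exclusions and variable-gene selection.
Removing low-coverage cells first means they cannot influence the size
factors.

* **QC**: cells with total UMI strictly below `min_cell_umi` (default 200)
  are discarded; afterwards genes with no count in any retained cell are
  dropped. The filter is idempotent.
* **Size factors**: per-cell total divided by the median of totals, so the
  median factor is exactly 1. For an even number of cells the median is the
  mid-mean of the central pair.
* **Transform**: `log10(count / factor + 1)`. The ambiguity between
  "normalize then log" and "log the raw count" is resolved as
  normalize-then-log, and the matrix carries a `transform` attribute
  recording normalization, base and pseudocount so the choice is auditable
  (and reversible for a dataset that needs the other convention).
* **Variable genes**: ribosomal genes (prefixes Rps/Rpl/Mrps/Mrpl) and an
  explicit cell-cycle list (shipped in `extdata`) are excluded, then genes
  are scored by a mean-CV noise model: mean and coefficient of variation are
  computed on the de-logged normalized values, the expected log CV at a
  gene's mean is a rolling median over mean-ordered genes (window
  `max(25, 1%)` of eligible genes), and the score is the observed minus
  expected log CV. The rolling-median fit is a deliberate choice: the
  functional form of the noise model is not prescribed, and a local median
  tracks the empirical mean-CV trend without committing to the Poisson
  `CV = mean^-1/2` shape (which is recovered anyway when the data are
  Poisson-like). The top 425 genes by score are kept, ties broken
  lexicographically so results are reproducible.

# Clustering and annotation

PCA runs on the variable genes, gene-centered but not variance-scaled
(scaling would undo the dispersion weighting the selection just
introduced); the first 40 components are kept and component signs are fixed
by making each component's largest-magnitude loading positive. The KNN
graph (k = 20, Euclidean distance in PC space) is symmetrized by edge
union with unit weights — the simplest construction consistent with an
undirected modularity optimization — and Louvain community detection runs
at resolution 1.0 with a seed-shuffled node order, so a (graph, resolution,
seed) triple always reproduces the same partition. No cluster count is
forced: annotation takes whatever Louvain yields, z-scores each cell type's
mean marker expression across clusters, and assigns the argmax type, with
ties and all-zero clusters labelled "ambiguous". A cluster that contains a
condition-specific cell state (the trained-monocyte subset, in the
simulation) therefore resolves to its parent type via the shared markers.

# Bulk kinetics and the integral-difference statistic

Bulk samples are normalized exactly like cells (total/median factors),
log2(x+1)-transformed, and floored at a minimal expression of 3 (4 is the
documented alternative for noisier designs); flooring precedes replicate
averaging so floors propagate into means. Replicates are averaged per
condition and timepoint, and for every gene the statistic is

$$D_g = \int \bar y_{g,\mathrm{trained}}(t)\,dt -
        \int \bar y_{g,\mathrm{control}}(t)\,dt$$

computed by the trapezoid rule over the observed days only (unequal spacing
respected, no extrapolation to day 0), in units of log2 · days. The D
values across all genes are approximately normal when most genes are
unresponsive; the null is fitted by the sample moments (a median/MAD
alternative sits behind `robust = TRUE`) and genes strictly exceeding
`mean + 3 SD` are called up-regulated due to training. Only up-calls are
made by default; the symmetric down-call exists behind a flag. On a
standard-normal D the 3-SD rule calls the expected one-sided tail fraction
(~0.00135), which the acceptance suite verifies by Monte Carlo.

Matched per-timepoint control samples are the default integration
baseline; a pooled control baseline can be emulated by averaging control
samples before building the time course, but is not the default because
matched controls absorb timepoint-level batch structure.

# Differential expression and enrichment

DEGs use classical tools: a pooled-variance two-sided t-test (Welch behind
a flag), one-way ANOVA for three or more groups, BH step-up FDR, and fold
filters — `|log2 FC| >= log2(min_fold)` for pairwise tests, maximal
pairwise ratio of de-logged group means for ANOVA. BH was chosen as the
FDR procedure; DEG counts depend on that choice, so it is stated
prominently. Zero-variance genes get p = 1 when group means agree (never
NaN). Fold filters also serve a second purpose on strongly induced
designs: a large planted (or real) induction shifts library composition,
and total-count normalization then imparts a small global shift to every
null gene that a well-powered pooled t-test will detect; the twofold floor
removes these composition artifacts. Multi-contrast analyses apply BH
within each contrast and report the union of passing genes, annotated with
the contrasts passed.

Enrichment is over-representation analysis: hypergeometric upper-tail
p-values of the overlap between a discrete gene list and each set of a GMT
collection, both intersected with the expression universe (all genes in
the prepared matrix), BH across sets. ORA is the standard discrete analog
of ranked gene-set enrichment for threshold-defined DEG lists; a ranked
permutation variant is deliberately out of scope.

# What the generators emulate — and what they do not

`simulate_sc_counts()` draws gamma-Poisson counts (negative binomial, size
2) with log-normal library sizes (`meanlog = log(1474)`, `sdlog = 0.9`,
giving a median library of ~1474 UMIs and ~1.5% of cells under the 200-UMI
cut), six cell types at fixed proportions over 768 cells per condition,
eight 8-fold markers per type (four carrying the shipped marker-table
symbols), and a 30-gene training program induced 4-fold only in trained
classical monocytes. Real ribosomal and cell-cycle symbols are included so
the exclusion rules are exercised. Not emulated: ambient RNA, doublets,
batch effects, cell-cycle structure — so passing tests demonstrate the
pipeline's correctness and parameter recovery under the stated noise
model, not robustness to those artifacts.

`simulate_bulk_timecourse()` plants responsive genes as piecewise-linear
templates on the day axis (early-transient peaking at day 14 and gone by
day 30; sustained rising by day 14 and holding; delayed rising only from
day 30), scaled by `effect_log2` on top of a Gaussian log2 baseline plus
0.3 log2 units of noise, and emits both the log2 matrix and rounded linear
counts. The defaults (5000 genes, 5% responsive, sustained, effect 3) are
the parameter-recovery conditions under which the 3-SD call achieves
sensitivity at least 0.95 with a false-call rate at most 0.01; transient
and delayed profiles have smaller integrals by construction and are
recovered at correspondingly lower rates, which is a property of the
statistic, not a defect of the implementation.

Truth tables are always written beside simulated data, and tests compare
against the written truth rather than regenerating it.

# Numerical choices and degenerate inputs

* Ties in variable-gene scores and in KNN distances are broken by gene id
  and column order respectively; PCA signs are canonicalized — three
  places where floating-point ties would otherwise make runs
  irreproducible.
* An SD-zero null in the training call warns and calls nothing; constant
  matrices are an error in PCA; missing values abort replicate averaging
  rather than being dropped.
* Config files are YAML; unknown keys are fatal rather than warnings so a
  typo cannot silently run a default analysis.

# Problem sizes

The shipped analyses and tests run at the simulated study scale: 1536
cells by 2000 genes for the single-cell layer and 5000 genes by 30 samples
for the bulk layer, with the null-calibration Monte Carlo at 100,000
genes. The full suite completes in well under a minute on one core.

# Known limitations

The noise-model fit assumes enough genes per mean window (at least ~25);
very small panels should use the Poisson baseline instead. The KNN graph
is built from a dense distance matrix, adequate to a few thousand cells
but not to atlas scale. The integral-difference null fit contaminates its
moments with the planted/real signal when a large fraction of genes
responds strongly; the robust (median/MAD) fit is the escape hatch there.
Count-model DE (negative-binomial GLMs) is deliberately not provided — the
procedures here operate on transformed data by design.
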