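---
title: "Methods: signature discovery for post-infarction heart failure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature discovery for post-infarction heart failure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the pipeline

After a myocardial infarction, a subset of patients progresses to heart
failure, and circulating immune cells carry transcriptional traces of that
trajectory. `hfsig` implements a discovery chain that starts from a
single-cell census of blood immune cells, asks *which cell types' disease
programs predict the bulk phenotype*, localizes the predictive program to a
cell subcluster, and distills it into a compact gene panel validated as a
classifier:

cell-type DE lists → over-representation against gene-set collections →
per-set classifier evaluation (screening rule) → single-sample scoring to
attribute the program to a subcluster → pooled candidate genes → cyclic
leave-one-out AUC refinement → final validation.

Each stage is exposed as one function with file-based inputs and outputs, so
any stage can run standalone on user data; `run_full_pipeline()` wires them
together on synthetic data with a known ground truth.

# Models and statistics

## Differential expression and markers

Counts are normalized as `ln(1 + 10^4 · x / colsum)`. Two-group DE is a
two-sided Wilcoxon rank-sum test behind two gates: an expression-fraction
gate (`min_pct = 0.1` in at least one group) and a log-fold-change gate
(`logfc_threshold = 0.25`), where `log_fc` is the natural-log fold change of
`expm1`-means — the convention of the single-cell toolkit whose defaults
these are, which makes the 0.25 threshold interpretable. p-values are exact
(full enumeration over mid-ranks) when both groups have at most 8
observations, and otherwise use the normal approximation with mid-ranks, tie
correction and continuity correction. BH adjustment runs over tested genes
only; results are ordered by decreasing |log_fc| with lexicographic
tie-breaks, because that ordering (truncated at 500) is what feeds
enrichment. Marker detection is one-vs-rest DE, direction "up", retaining
`p_adj < 0.05`.

## Enrichment

Over-representation is the one-sided upper-tail hypergeometric test of the
query against each set, both intersected with the universe. The universe
defaults to all genes measured in the data the query came from (carried as
an attribute of every DE result) and is configurable — the web tools that
popularized this analysis leave the universe implicit, so it is stated and
logged here. BH runs **within one collection category at a time** (GOBP,
KEGG, ...), since results are compared per collection. The default output
truncation (`q < 0.05`, top 10) mirrors those tools' display defaults and is
applied *before* the screening count by default (a flag disables it).

Preranked enrichment uses the weighted Kolmogorov–Smirnov running sum with
weight `|score|` (exponent 1). Because the input is a preordered list, the
null is a seeded gene-label permutation (phenotype permutation is not
available); p-values are sign-aware with a +1 correction and the normalized
ES divides by the mean |permuted ES| of the same sign.

## Single-sample scores

The per-sample, per-set activity score follows the published gene-set
variation analysis construction: (i) each gene's expression is transformed
to a kernel-smoothed CDF estimate across samples — Gaussian kernel with
bandwidth `sd/4` for continuous data, Poisson kernel (`λ = x + 0.5`) for
counts, or the exact ECDF; (ii) within each sample genes are ranked by that
statistic and the rank is symmetrized (`|n/2 − rank|`) to up-weight both
tails; (iii) a weighted KS random walk over the sample's gene ranking yields
the score — by default the sum of the largest positive and largest negative
deviations (`max_diff`), with the signed maximum deviation
(`two_sided_max`, bounded in [−1, 1]) as the alternative.

Numerical choices: within-sample rank ties break by gene order
(`ties.method = "first"`), making the walk deterministic; constant genes get
a flat CDF of 0.5; a set covering the whole universe scores 0 and a set with
no measured member is skipped with a warning. `kcdf = "auto"` selects the
Gaussian/Poisson kernel up to 200 columns and the exact ECDF beyond, because
the kernel estimate is O(n²) per gene and the ECDF is its small-bandwidth
limit — this is what makes scoring thousands of cells affordable.

One property worth stating precisely: for a one-gene set the score is
`1 − 2(pos − 1)/(n_genes − 1)`, a strictly decreasing function of the gene's
*within-sample* rank position. The score ordering across samples therefore
reproduces the gene's within-sample rank ordering exactly; it coincides with
the gene's cross-sample expression ordering only when the other genes do not
reshuffle within-sample positions, which is not guaranteed in general.

## Classification and validation

The classifier is a two-class nearest centroid: per-class mean expression
over the feature genes; the continuous prediction score of a sample is
`d(x, negative centroid) − d(x, positive centroid)` (euclidean by default,
correlation distance available). Evaluation uses multiple random validation:
`n_splits` stratified train/test partitions at `train_fraction` per class
(rounded, clamped so both folds keep both classes). Each sample's held-out
scores are pooled into **one score per sample** (the mean over the splits in
which it was held out, with the count recorded). From those per-sample
pooled scores come: the ROC (thresholds swept over distinct scores with tie
groups, so the trapezoidal area equals the Mann–Whitney statistic with
half-credit ties, exactly), the Welch-t ROC p-value, the Hanley–McNeil
binomial 95% CI for the AUC, and sensitivity/specificity at the max-Youden
threshold with Wilson 95% intervals.

Per-sample pooling is a deliberate design decision. Pooling at the
occurrence level (every held-out appearance as its own observation) inflates
the Welch statistic by roughly the square root of the average hold-out
count, because the same sample's scores are strongly correlated across
splits; the per-sample version is consistent with p-values of the magnitude
the motivating framework reports on cohorts of this size. A caveat remains
either way: across many overlapping splits, different samples participate in
each other's training folds, which induces positive same-class score
correlation, so the Welch-t ROC p is anti-conservative under a feature-null
when `n_splits` is large. At `n_splits = 1` the held-out scores are
independent of the held-out labels under the null and the p-value is
calibrated — the package's null-uniformity tests run there. Screening
results are therefore comparative (signal sets versus null sets within one
BH family), not absolute null-calibrated claims.

Defaults `n_splits = 200` and `train_fraction = 2/3` are not sourced from
the motivating study (which does not state them); they are the cited
framework's conventional settings, logged in every report, and configurable
everywhere. The heavy simulation loops in the test suite use 50 splits — a
precision knob for the AUC estimate chosen up front for runtime, not an
effect size.

## Screening rule

A cell type passes one bulk cohort when at least half of its enriched sets
reach ROC FDR < 0.05, where the ROC FDR is the BH adjustment of the per-set
Welch-t ROC p-values *within that (cell type, cohort) set list*. "Not less
than half" is evaluated as `n_significant / n_enriched ≥ 0.5`, the literal
reading (1 of 2 passes, 2 of 5 fails). A cell type with no enriched sets
fails with the recorded reason rather than raising. The final screened set
is the intersection of passing cell types across cohorts.

## Cyclic leave-one-out refinement

The candidate pool is the union of all gene sets with adjusted ROC p < 0.05,
deduplicated and sorted. Each cycle forms **all** `n` leave-one-out subsets
of the current `n`-gene list — the description "n−1 combinations selected
randomly" in the motivating text is read as the sampling of validation
splits inside the AUC evaluation, the only reading consistent with "of
these n combinations" and a strictly shrinking list; a `subset_sample` flag
enables random subsampling of subsets for very large pools. Within a cycle
every subset is evaluated against the same pre-drawn split sequence so AUC
differences reflect gene content, not split noise; each cycle draws fresh
splits from the seeded stream. The best subset (ties broken toward the
lexicographically largest left-out gene — deterministic and content-based)
advances; recursion stops when three genes remain.

For the euclidean distance the evaluation is vectorized: per-gene squared
distance contributions to each centroid are computed once per split and
subtracted from the full-list totals, which is algebraically identical to
refitting each subset (a unit test checks exact agreement with the generic
path and with an independently coded brute-force oracle on pools of ≤ 6).

Selection: the reported signature is the gene list at the **smallest size
attaining the global maximum AUC** (`largest_max` selectable). When effects
are strong the in-sample AUC saturates at 1 over a wide size range and the
rule picks a very small panel; the size-vs-AUC table in the trace reports
the whole curve, and the ground-truth recovery analyses read the trace at
the reference panel size (13) — the point where the elimination should have
discarded all decoys — rather than at the selected size. The selected
signature's headline AUC is computed on an independent held-out cohort
generated with a fresh seed, because an AUC maximized by the refinement
itself is optimistic by construction; the in-sample value is reported too,
flagged as in-sample.

# The synthetic world

The generator states one fixed world rather than exposing a dial per test:
a shared universe of 2,000 genes; five immune subclusters (three B-cell, one
NK, one monocyte) of 200 cells; 50 planted markers per cluster at a log2
shift of 2 (additive on the log scale, multiplicative on raw counts — the
simplest model matching logFC-based detection); bulk cohorts of 40 + 40
samples whose 13-gene panel is shifted by 2 standard deviations of each
gene's log-scale spread in the positive class; 3 planted-enrichment sets
(≥ 80% planted members) among 30 null sets of 25 genes. Baselines are
log-normal on the log2 scale (array-like) with per-gene means and
dispersions drawn from stated hyperpriors, or negative-binomial counts
(10x-like). Cluster `k`'s markers occupy the `k`-th disjoint gene block and
the bulk panel is the first 13 genes, so the first cluster is the
signal-bearing subcluster and links the single-cell and bulk worlds; the
sample sizes mirror the bulk cohorts of the motivating design. Condition
labels are assigned at donor level (cells inherit them) with no planted
condition effect — the per-cell-type DE lists used by screening are
one-vs-rest marker lists.

What the generator does **not** emulate: ambient RNA, doublets, batch
effects, library-size confounding, donor random effects on expression,
correlated gene modules beyond the planted ones, or realistic subcluster
counts (the motivating data had 27). A green test therefore establishes the
statistical machinery — gates, tests, adjustments, the screening decision,
the elimination dynamics — under clean planted structure; it does not
certify performance on real blood transcriptomes.

# Determinism and provenance

One master seed drives everything; each consumer derives a child seed by a
fixed offset, so sub-simulations are independently reproducible and a rerun
with the same configuration produces byte-identical outputs (TSV writers use
fixed formatting, JSON reports a pinned schema). The run manifest records
the normalized configuration, the seed ledger, and an md5 registry of every
output file; stage timings go to a separate `timings.tsv` precisely so the
manifest itself stays byte-stable across reruns.

# Known limitations

* The Welch-t ROC p inherits the anti-conservativeness of pooled
  multiple-random-validation scores at large split counts (discussed above).
* The null-collection enrichment p-values are valid but discrete
  (sub-uniform), so uniformity is checked as `P(p ≤ α) ≤ α` bounds rather
  than a literal KS test.
* No multiclass support, no covariate adjustment, no consensus DE across
  engines (the DE interface is pluggable for that purpose), no gene-id alias
  resolution: identifiers are opaque case-sensitive strings.
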