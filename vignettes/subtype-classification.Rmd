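---
title: "Ensemble sparse random projections for molecular subtype classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble sparse random projections for molecular subtype classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpsubtype)
```

## The problem

B-cell acute lymphoblastic leukemia (B-ALL) comprises roughly twenty
molecular subtypes — fusion-gene events (Ph, Ph-like, ETV6-RUNX1, ...),
transcription-factor alterations (PAX5alt, IKZF1 N159Y, ...), ploidy
changes (high hyperdiploid, near haploid, ...) and rare entities
(BCL2/MYC, NUTM1, HLF) — whose identification drives risk stratification
and treatment choice. Bulk RNA-seq carries enough signal to call the
subtype, but an expression matrix has tens of thousands of gene features
for at most a few thousand patients, and the subtype distribution is
heavily imbalanced: in large reference cohorts the three dominant
categories alone cover roughly 45% of patients while several categories
have fewer than ten.

`rpsubtype` addresses this with a three-stage pipeline:

1. **Preprocessing** to a common representation, `log2(TPM + 1)`, from raw
   counts, FPKM or TPM, after a gene prevalence filter.
2. **Very sparse random projection** of the gene dimension `D` down to
   `d` dimensions, repeated `M` times with independent seeds.
3. An **ensemble of linear SVM classifiers**, one per projection, whose
   calibrated per-class probabilities are averaged into the ensemble score.

A fourth component reuses the model output for **prediction-informed 2-D
visualization**: the projected features and the one-hot predicted labels
are z-scored, weighted, concatenated, and embedded.

## Preprocessing

Genes are kept when they are expressed (value strictly above a
configurable cutoff, default 0) in at least a fraction `min_fraction`
(default 0.75) of samples; the count is compared against
`ceiling(min_fraction * N)` so "at least 75%" holds literally. Counts are
converted to TPM with caller-supplied effective gene lengths (no
annotation is bundled, and the length definition — union exon vs
transcript — is deliberately left to the caller); FPKM is renormalized
per sample to sum to one million, which makes TPM a fixed point of the
conversion. The log transform is `log2(TPM + 1)`.

Subtype labels are harmonized by `harmonize_labels()` with a
`subtype_scheme`: the default `ball_scheme()` carries the 20 categories,
merges the small "-like" categories ZNF384-like and KMT2A-like into their
parent groups, excludes CRLF2(non-Ph-like), and drops samples annotated
"other" or carrying two subtype calls. The prevalence filter is applied to
the training cohort after sample exclusion.

At prediction time incoming matrices are aligned to the training gene
list by identifier; if fewer than 90% of training genes are present the
call errors, and zero-filling of missing genes is available only behind
an explicit flag, because silently zero-filled genes perturb every
projection they load on.

## The projection

The projection matrix `R` (d × D) has i.i.d. entries

* `+sqrt(p)` with probability `1/(2p)`,
* `0` with probability `1 - 1/p`,
* `-sqrt(p)` with probability `1/(2p)`,

which gives mean 0 and variance 1 for any `p >= 1`, so `A = (1/sqrt(d)) R T`
preserves squared pairwise distances in expectation
(Johnson–Lindenstrauss). We default to the very-sparse recommendation
`p = sqrt(D)`, under which only a fraction `1/sqrt(D)` of entries are
nonzero (about 0.7% at `D ≈ 21,600`); `p` is exposed as a knob, and
`p = 1` recovers a dense Rademacher matrix. The `sqrt(p)` magnitude is
folded into the stored sparse matrix so `A` is exactly `(1/sqrt(d)) R T`.
Distances are Euclidean on the `log2(TPM+1)` features with no further
standardization.

`distance_pcc()` quantifies preservation as the Pearson correlation
between original and projected pairwise sample distances, and
`dimension_sweep()` repeats it over target dimensions and seeds (with a
PCA adapter for comparison). On clustered Gaussian data
(`D = 2000`, `N = 100`, five separated centers) the correlation exceeds
0.95 already at `d = 100` and approaches 1 by `d = 1200`, increasing with
`d`; this mirrors what matters in cohort data, where between-subtype
separation dominates the distance spread. On data with no structure at
all (i.i.d. isotropic noise) all pairwise distances concentrate around a
single value and the correlation is necessarily much lower — the
diagnostic measures preservation of *structure*, not of noise.

## The ensemble classifier

`rp_ensemble(x, y, d = 1200, M = 30, seed)` draws `M` independent
projection matrices (member `m` uses seed `seed + m`), projects the
training data, and fits per member one linear SVM per class
(one-vs-rest, cost default 1). The defaults `d = 1200`, `M = 30` are
the stable operating point of the method at full cohort scale.

Per-class margins are calibrated into probabilities with a Platt sigmoid
fitted on the training margins using the standard smoothed targets
`(n+ + 1)/(n+ + 2)` and `1/(n- + 2)`; the smoothing keeps the logistic
fit finite even when the margins separate the classes perfectly, and the
unconstrained slope absorbs the margin sign. The fit uses a plain
quasibinomial GLM, so the whole training path is deterministic: identical
data and seed reproduce the model and its predictions bit for bit. The
calibrated per-class sigmoids are renormalized to a distribution per
member, and the ensemble score is the average over members — hence each
score row sums to 1, the score is bounded by the member minima/maxima,
and an `M = 1` ensemble is exactly its single member. Raw-margin
averaging (uncalibrated) is available via `predict(..., type = "margin")`.
Ties in the argmax go to the first class in the (alphabetical)
class order. Calibration on the training margins is mildly optimistic
compared to a held-out calibration fold; since scores are only averaged
and ranked, this does not affect the argmax decision rule materially, and
it keeps every member's training deterministic and cheap.

Class-imbalance weighting and post-projection feature standardization
exist as flags, both off by default. Projections are data-independent, so
in cross-validation the projection seeds are shared across folds while
classifiers are refit per fold; no information can leak through a random
matrix that never saw the data.

Why an ensemble: a single random projection is an unbiased but noisy
representation; different projections make partially independent errors,
and averaging their calibrated probabilities both raises mean accuracy
and shrinks its variance across datasets. The package restates this
testably: over 20 simulated replicates at moderate effect size, the
`M = 30` ensemble's cross-validated accuracy exceeds the mean
single-projection accuracy (paired one-sided Wilcoxon, α = 0.05) and its
across-replicate variance is no larger than that of the pooled individual
members. "Individual accuracy" is defined per replicate as the mean of
the members' own CV accuracies, and the variance comparison pools all
members across replicates — the natural reading of an
ensemble-vs-individual box-plot comparison.

## Evaluation

`binary_metrics()` implements the one-vs-rest definitions of accuracy,
F1 (`2TP / (2TP + FP + FN)`, independent of TN) and the Matthews
correlation coefficient, with MCC defined as 0 whenever a factor of the
radicand vanishes. Aggregates over classes are reported both ways where a
convention had to be chosen:

* **F1**: support-weighted by default (robust under heavy imbalance),
  macro alongside.
* **MCC**: Gorodkin's multiclass generalization by default, the mean of
  per-class one-vs-rest MCCs alongside.

Per-class "accuracy" in the headline sense of subtype recovery is the
recall (confusion-matrix diagonal over row sum); the `per_class` table
carries TP/FP/TN/FN, one-vs-rest accuracy, F1, MCC, recall and support.

`repeated_cv()` runs stratified k-fold CV (default `k = 5`), re-randomized
per repeat, dealing each class's shuffled samples to folds in rotation so
per-fold class proportions are within one sample of the target; classes
smaller than `k` occupy fewer folds and trigger a warning.
`holdout_split()` draws a stratified test set of `round(fraction * N)`
samples via largest-remainder allocation, never emptying a class's
training side. `group_metrics()` rolls the confusion matrix up into the
four subtype groups (Fusion Gene, TF Alteration, Ploidy, Rare Subtype):
for each group the rows of its member classes are kept with within-group
columns resolved per class and all outside predictions collapsed into one
column, and the aggregate metrics are computed on that sub-confusion.

## Visualization

`build_vis_matrix()` z-scores the projected feature block (by default the
first ensemble member's projection) and the one-hot predicted-label block
column-wise and concatenates them as `[w·Z(F) | Z(Y)]`. The z-score uses
the sample (divide-by-`N-1`) standard deviation — R's `sd()` — and the
convention is recorded on the result; constant columns map to zeros. The
weight ratio `w` (default 1) trades global expression geometry (`w > 1`)
against predicted subtype identity (`0 < w < 1`).

The 2-D embedding backend is pluggable, and the construction above — the
part that carries the method — is backend-independent. The default
backend is classical multidimensional scaling (`cmdscale`), which is
fully deterministic and preserves the global distance structure the
visualization matrix encodes; nonmetric MDS (`MASS::isoMDS`) is available
as `method = "nmds"`. The recorded neighborhood parameter defaults to
`min(30, (N-1)/3)` for backends that use one. The property the
construction is designed for — that appending the prediction block raises
the silhouette of the true classes in the embedding relative to the
feature block alone — is asserted over 20 seeded simulations in the test
suite and holds in essentially all of them.

## The synthetic cohort generator

`sim_expression()` emulates the features of a bulk RNA-seq subtyping
cohort that the pipeline actually exercises: a shared log-normal baseline
(log2-mean 4, sd 1.5), disjoint marker blocks per class shifted by
`effect_size` on the log2 scale, per-entry Gaussian log-scale noise,
per-sample library-size variation, Poisson counting at ~2M reads per
sample, and a zero-inflated gene fraction (20% of non-marker genes at 60%
dropout) that the 75% prevalence filter removes almost entirely. Markers
are planted on the brighter half of the baseline distribution, because a
log2 shift on a barely-expressed gene survives neither TPM
renormalization nor Poisson counting — a property of real marker genes
too. Counts (not TPM) are generated so the full preprocessing path is
exercised, with gene lengths emitted alongside.

`make_cohort_like()` instantiates a desk-scale cohort: 20 classes named
after the default scheme's categories, head proportions 18.6% / 15.4% /
10.8% with a tapering tail floored at 5 samples, ~500 samples, 5,000
genes, marker effect 4. What the generator does *not* emulate — and what
passing tests therefore do not show about real cohorts — includes
gene–gene co-expression structure, fusion-transcript signal, batch
effects, and inter-subtype similarity gradients (simulated classes are
mutually equidistant in marker space, so confusions between biologically
adjacent subtypes such as Ph and Ph-like are not reproduced).

## Numerical choices and problem sizes

* MCC zero-denominator → 0; F1 zero-denominator → 0.
* Platt calibration falls back to a unit-slope sigmoid around the mean
  margin if the GLM degenerates (constant margins).
* All seeded functions restore the caller's RNG state; ensemble member
  `m` uses `seed + m` reduced into 32-bit integer range.
* Tie-breaks: argmax ties to the first class in alphabetical order;
  duplicate sweep dimensions are collapsed sorted.
* Degenerate inputs error early: empty expression files, duplicate ids,
  negative values, all-zero distance vectors, classes with fewer than two
  samples.

The shipped test and acceptance workloads run the method at desk scale,
chosen so each property is measured with comfortable Monte-Carlo margins:
projection moments at `d·D ≥ 10^5` cells, norm preservation over 1,000
draws, distance preservation at `D = 2000, N = 100` over 10 seeds,
ensemble dominance over 20 replicates of a 100-sample 4-class cohort
(`d = 100`, `M = 30`), end-to-end recovery on the ~500-sample cohort-like
fixture (`d = 300`, `M = 10` — scaled with the 4,000-gene feature space),
and the silhouette property over 20 seeds. Full-cohort operating points
(`d = 1200`, `M = 30`, 100×5-fold CV) remain the function defaults.

## Known limitations

* No batch-effect correction; matrices from different platforms or
  centers should be harmonized upstream.
* No "unclassified" call: the argmax label is always emitted, with the
  row-maximum score as a confidence column for downstream thresholding.
* Calibration quality for very small classes (fewer than ~5 positives) is
  limited; their probabilities are usable for ranking but not as
  frequencies.
* The model archive format is R-native serialization with a version tag;
  it is not designed for cross-language interchange.
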