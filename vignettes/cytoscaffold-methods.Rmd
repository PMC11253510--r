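---
title: "Models and methods behind cytoscaffold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cytoscaffold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery of `cytoscaffold`: the
annotation model, the DREMI estimator, the rebalancing and modeling
protocols, what the synthetic generator does and does not emulate, and the
design decisions taken where the methodology was genuinely open.

## Data model and preprocessing

The central container, `CytoExpression`, holds a cells-by-markers matrix
of protein intensities with optional per-cell type labels and sample ids,
following the events-by-parameters orientation of cytometry tooling.
Intensities are assumed arcsinh-transformed; `arcsinhTransform()` applies
`asinh(x / c)` with cofactor `c = 5`, the community convention for metal
isotope detectors (the cofactor is configurable; fluorescence data would
use ~150). Negative values left by upstream bead normalization are
transformed as-is, not truncated: truncation would bias the per-sample
medians used as baseline features. Double transformation is an error
unless forced.

Panel harmonization (`harmonizePanels()`) is exact string intersection of
canonical marker names after applying a user alias map, ordered by the
reference panel. No fuzzy matching is attempted: a silently mismatched
antibody is far more damaging than a loud error. Reference datasets are
filtered with `filterReference()` (default 300 cells per type): below
that, a cell type's landmark is dominated by sampling noise.

A minimal read-only FCS 3.0/3.1 parser handles list-mode float data; the
delimited text format uses a marker-name header plus reserved
`__label__`/`__sample__` columns and round-trips to 1e-9.

## Reference-guided annotation

Annotation proceeds in four steps:

1. **SOM clustering** (`trainSOM()`): an online self-organizing map on a
   10×10 grid (Gaussian neighborhood; 10 passes; learning rate decaying
   linearly 0.05 → 0.01; radius decaying from half the larger grid
   dimension to 0.3, so late updates are effectively winner-only;
   codebook initialized from a seeded random sample of cells). All
   stochastic steps are driven by an explicit seed and training is
   bit-reproducible. The final radius matters: a final radius of ~0.5
   leaves enough neighbor coupling that adjacent nodes are pulled several
   tenths of a unit toward each other's clusters, visibly biasing
   centroids; 0.3 makes the residual coupling (≈ exp(−1/0.18)) negligible.
2. **BMU assignment** (`assignToNodes()`): nearest codebook vector by
   Euclidean distance, ties to the lowest node index.
3. **Landmarks** (`computeQueryLandmarks()`, `computeReferenceLandmarks()`):
   cluster centroids over the backbone markers; empty nodes produce no
   landmark. Reference landmarks are per-type arithmetic means (the
   "centroid" notion; a median option exists for heavy-tailed references).
4. **Matching**: cosine similarity between every query landmark and every
   reference landmark; each cluster and its member cells inherit the
   argmax label, ties broken toward the first reference label in sorted
   order — determinism over elegance. An optional similarity threshold
   relabels weak matches `"unassigned"`; the default is no threshold,
   since a well-calibrated cutoff is cohort-dependent.

By default each query sample is clustered independently (matching
per-patient annotation practice and keeping per-sample batch structure out
of the codebook); `pooled = TRUE` clusters all cells jointly, which is
what the self-consistency protocol uses on a single reference. Cosine
matching makes assignments invariant to any global positive rescaling of
the backbone intensities.

Supervised per-cell baselines: Euclidean-distance KNN majority vote (vote
ties resolved by the nearest neighbor's label) and `MASS::lda` posteriors
with no rejection threshold.

`selfConsistencyProtocol()` evaluates methods on a stratified 80/20 (or
50/50) split of a labelled reference, scoring each cell type one-vs-all.

## The DREMI estimator

`dremiScore(x, y)` estimates, in bits, how much the conditional
distribution of Y moves across states of X:

1. a Gaussian KDE (via `MASS::kde2d`) of the joint density on a 256×256
   grid spanning each axis's range expanded by one bandwidth, normalized
   to total mass 1;
2. block-sum aggregation to an 8×8 coarse grid;
3. each X column with mass ≥ 1% of the uniform column mass (1/8) is
   renormalized into `p(y|x)`; sparser columns are excluded;
4. retained X states receive *equal* weight `w(x)` — an exact,
   deterministic version of the density-resampling idea (identical in
   expectation to stochastic resampling, without its variance) — and the
   score is `Σ_x w(x) Σ_y p(y|x) log2[p(y|x)/q(y)]` with
   `q(y) = Σ_x w(x) p(y|x)`, clipped to `[0, log2 8]` (the cap is exact
   for the discrete form).

**Bandwidth.** The default bandwidth is one fine-grid cell width per axis
(range/256): the KDE then acts as a mild regularizer of the fine histogram
before coarse aggregation. A classical Silverman bandwidth is also
offered, but it is deliberately *not* the default: at n = 10⁴ Silverman's
rule gives ≈ 0.04 × range, the same order as a coarse bin (range/8), and
the resulting cross-bin leakage caps the score of a noise-free functional
relation Y = X near 1.9 bits instead of the theoretical 3 — a systematic
downward bias of exactly the conditional structure the statistic exists to
measure. With the grid-scaled default, independent inputs at n = 10⁴ score
≲ 0.01 bits (finite-sample MI bias at 8×8 is ≈ 49/(2n ln 2)), a
deterministic relation scores ≥ 2.78 bits, and the score is monotone in
the strength of a linear dependence. Because the grid and bandwidth scale
with the data range, strictly increasing affine maps of either marker
move the score only marginally.

Estimation needs at least 200 cells (`minCells`); patients with fewer
cells of a type are *masked*, never imputed — imputing a mutual
information would manufacture the very signal being tested. Non-finite
values are dropped pairwise. Settings travel with every result
(`DremiParams` inside `DremiResult`) for provenance.

`dremiFromJoint()` exposes the exact discrete form on a coarse joint
matrix; it is validated against independent direct summation and anchors
the estimator's correctness tests.

## Feature engineering

Per cell type and per sample: `medianFeatures()` gives one feature per
signaling marker (mean-of-middle convention for even counts);
`dremiPairFeatures()` gives all p(p−1) ordered pairs — both directions
scored separately, since D(X→Y) ≠ D(Y→X) — in lexicographic order of the
configured signaling panel, so feature columns are stable across runs and
cohorts. A 15-marker panel yields 210 directed features.

## SMOTE rebalancing

`smoteResample()` is stated in terms of the *final class ratio* rather
than over/under-sampling percentages, because the ratio is the quantity a
study reports. For target ratio `a:b` (minority:majority) with nMin
minority and nMaj majority samples:

- final minority count `m = max(nMin, ceiling(nMaj·a/b))` — original
  minority points are always retained and synthetic points are added up to
  `m`; each synthetic point is `s = a + u(b − a)`, `u ~ U(0,1)`, between a
  minority point and one of its k = 5 nearest minority neighbors, so all
  synthesis stays inside the minority convex hull;
- final majority count is exactly `m·b/a`, drawn without replacement when
  that many majority cases exist and topped up by resampling with
  replacement when the exact ratio requires more (the behavior of the
  classical R implementation) — on the 15/28 cohort shape the three
  studied ratios come out as 28/28, 15/30 and 15/45.

SMOTE is applied to the *training partition only*, never to validation or
test data: rebalancing before the split would leak synthetic copies of
test-adjacent minority points into training. The estimator is
deterministic given its seed.

## Survival modeling protocol

One repeat of `repeatedProtocol()`:
stratified split (`splitHoldout()`: test = 20% or 50%; validation = 40% of
the remaining pool; a split missing a class anywhere is redrawn, up to 100
attempts) → optional SMOTE on train → `tuneAndTrain()` → test-set metrics.
XGBoost tunes only the maximum tree depth over
{2,4,6,8,10,12,14,16,18,20,30,40,50,60}, maximizing validation F1 with
ties to the smallest depth; other boosting parameters are pinned (100
rounds, η = 0.3, binary logistic) and configurable. Lasso (α = 1) and
ridge (α = 0) follow glmnet's standard convention; the penalty is chosen
on the same F1 criterion with ties to the largest penalty. The positive
class defaults to STS (predicting short survival is the clinically urgent
call) and SEN/SPE/F1 use a 0.5 probability threshold; AUC is
threshold-free midrank Mann–Whitney.

`runCellTypeModels()` drives the protocol over per-cell-type feature
matrices (100 repeats × 7 cell types = 700 classifiers), and
`aggregateImportance()` summarizes boosters by selection count (runs using
the feature at least once) and mean gain, sorted by (count, gain).
`stratifyByMedian()` provides the cohort-median split (ties to "low") used
to hand groups to standard survival routines (Kaplan–Meier/Cox in the
`survival` package); those analyses themselves are deliberately out of
scope.

## Evaluation

Multiclass annotation is scored one-vs-all per cell type: TP/TN/FP/FN →
ACC, SEN, SPE, F1. A metric with a zero denominator is reported as `NA`
("undefined"), never as 0 — folding zeros into macro averages silently
punishes rare classes. Macro averages are unweighted over classes with
defined values; per-class values are always retained.

## The synthetic generator

`syntheticSpec()` defines a ground-truth study; its defaults mirror the
shape of a leukemia cohort study: 7 cell types, a 15-marker backbone and
15-marker signaling panel, 28 short-term and 15 long-term survivors, a
60-month survival cutoff, 2 000 cells per sample, within-type standard
deviation 0.2 in arcsinh space, and type profiles drawn at pairwise cosine
similarity ≤ 0.7 (each type expresses a random third of the backbone
highly, ~2.5–4 arcsinh units, the rest at baseline; drawing retries until
the cap holds). Per-sample abundances follow a Dirichlet (concentration 5
per type — moderate, realistic between-patient variation). Planted
dependencies overwrite the downstream marker as
`y = β_group · f(x) + ε` per survivor group, with `f` linear or a
saturating sigmoid. Survival months are drawn uniformly on either side of
the cutoff.

What passing tests on these data do show: the pipeline recovers cluster
structure, directed dependencies, and group differences it was built to
detect, at realistic cohort sizes and noise. What they do not show:
robustness to heavy-tailed marginals, batch effects, doublets, acquisition
drift, or imperfect upstream gating — none of which the generator
emulates, and all of which real cohorts contain.

Two design points deserve emphasis:

- **Direction identifiability.** Mutual information is symmetric; DREMI's
  directionality comes only from resampling along the conditioning axis.
  For an invertible linear dependence, X→Y and Y→X scores are nearly
  equal, *both* directions separate the groups, and no classifier can
  prefer the planted direction over its reverse — the recovery experiment
  therefore plants a *saturating* (sigmoidal) response, whose forward
  conditional stays tight while the reverse conditional widens at
  saturation. This mirrors real signaling saturation and makes direction
  recovery a well-posed question.
- **Recovery experiments use generator labels.** The planted-pair
  experiment feeds true cell labels to the feature stage, isolating
  feature engineering + modeling; annotation fidelity is established
  separately (self-consistency F1 ≥ 0.99 at the default separation), so
  routing through the annotator would only add runtime, not information.

## Numerical choices, tie-breaks, degenerate inputs

- BMU ties → lowest node index; landmark-similarity ties → first reference
  label in sorted order; KNN vote ties → nearest neighbor's label; depth
  ties → smallest; lambda ties → largest; median-split ties → "low".
- DREMI scores are clipped at 0 from below (numerical noise) and capped at
  log2(nCoarseBins); zero-variance axes, all-columns-excluded grids, and
  sub-minimum cell counts are errors, not silent zeros.
- Zero vectors have no direction: cosine similarity errors rather than
  returning 0.
- All generators, splits, SOMs and resamplers take explicit seeds; a
  pipeline run derives per-stage seeds from one global seed
  (`deriveSeed()`, kept below 2^31), so any stage reproduces in isolation.

## Problem sizes used in the validation experiments

The shipped experiments run at desk scale, chosen to exercise every code
path at the study's cohort shape: references of 7 × 1 000 cells for
self-consistency; cohorts of 43 samples (28/15) with 900–2 000 cells per
sample; DREMI calibration at n = 10 000 (independence/determinism) and
n = 2 000 × 20 seeds × 4 effect sizes (monotonicity); recovery over 10
generator seeds × 30 protocol repeats with a 4-marker signaling panel (12
directed features). Full-cohort analyses (millions of cells, 210
features, 1 000 repeats) use identical code paths and scale linearly.

## Known limitations

- Annotation quality is bounded by reference quality and panel overlap; a
  backbone of very few shared markers yields ambiguous landmarks, and rare
  populations absent from the reference can only be mislabelled (no
  novelty detection without a similarity threshold).
- The DREMI hyper-parameters (grid sizes, bandwidth rule, column-mass
  cutoff) are estimator settings, not universal constants; cohort-level
  score values are comparable only under identical settings, which is why
  every result records them.
- The SMOTE exact-ratio rule duplicates majority samples when the ratio
  demands more majority cases than exist; heavy duplication (e.g. 1:3 on a
  15/28 cohort) narrows the majority's effective diversity.
- With ~40 samples, repeated hold-out estimates have substantial variance;
  the per-repeat distributions returned by `repeatedProtocol()` should be
  inspected, not just their means.
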