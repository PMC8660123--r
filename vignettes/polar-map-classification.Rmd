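---
title: "Classifying myocardial-perfusion polar maps with band-slicing features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying myocardial-perfusion polar maps with band-slicing features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polarSlice)
```

## The problem

Myocardial-perfusion SPECT studies are routinely summarised as *polar maps*
(bull's-eye plots): a two-dimensional circular projection of the left
ventricle with the apex at the centre, the base at the rim, and tracer
uptake encoded as pixel intensity. A perfusion defect — a territory of
reduced uptake, suggestive of coronary artery disease — appears as a darker
angular sector of the disc. `polarSlice` implements a complete, auditable
pipeline for the binary reading task: label a polar map *normal* (1) or
*abnormal* (0) from its pixel intensities alone.

The pipeline has five stages, each exposed as ordinary functions:

1. **Synthetic map generation** (`simulatePolarMaps()`) — a controlled
   stand-in for clinical archives.
2. **Feature extraction** (`extractFeatures()`, `buildFeatureMatrix()`) —
   the band-slicing projection described below.
3. **Minority-class augmentation** (`augmentNormals()`) — rotated copies of
   normal maps, applied inside training folds only.
4. **Stratified, leakage-audited k-fold cross-validation** (`runCV()`).
5. **Ensemble classification and metric reporting** (`trainModel()`,
   `computeMetrics()`, `aggregateMetrics()`).

## Band-slicing features

Each square map is cut into five contiguous horizontal bands (top to bottom,
`h1..h5`) and five vertical bands (left to right, `v1..v5`); the pixel
intensities within each band are summed, giving a 10-dimensional feature
vector per image and, with the label appended, an 11-column feature matrix.
For the canonical 175-pixel maps every band is exactly 35 pixels wide.

Two conventions are deliberately fixed and documented because the projection
is otherwise ambiguous:

* **Band boundaries.** Equal contiguous bands; for side lengths not
  divisible by five, a near-equal integer partition with the remainder
  pixels assigned to the trailing bands. Equal partition is the only reading
  consistent with a regular slicing grid.
* **Ordering.** Row 1 is the top of the image; `h1` is the topmost band and
  `v1` the leftmost. Any fixed convention would do — reproducibility
  requires naming one.

Because every pixel falls in exactly one horizontal and one vertical band,
the features conserve total intensity: `sum(h) == sum(v) == sum(pixels)`,
exactly, in the integer arithmetic of 8-bit images (the largest possible
band sum, 35 × 175 × 255, is far below the 2^53 limit of exact double
arithmetic). The test suite asserts this conservation law on a thousand
random images, and checks the band sums against a naive per-pixel oracle.

Band sums also transform predictably under quarter-turn rotations — a 180°
turn reverses the order within `h` and within `v`; a 90° turn maps the `h`
sums onto (reversed) `v` sums — which is what makes rotation a useful,
feature-changing augmentation.

## Synthetic data: what it emulates, and what it does not

The generator draws a centred uptake disc (radius 0.48 of the image width,
so any rotation keeps it inside the frame) on a dark background. Normal maps
get a per-map baseline intensity (mean 150 of 255, SD 10 across maps —
between-patient variation) plus per-pixel noise (SD 8). Abnormal maps
additionally receive 1–3 angular-sector defects, each spanning 30–120
degrees with full radial extent, whose pixels are multiplied by
`1 - severity` with severity drawn from 0.3–0.8. These defaults were chosen
once, as a regime in which defects are conspicuous to the features but
single maps are not trivially separable at the low end (a 30° sector losing
30% of its intensity moves two or three band sums by a few percent, around
noise of similar magnitude).

Dataset structure mirrors a referral archive with a pronounced class
imbalance: 108 normal and 899 abnormal maps by default, assembled patient by
patient — two maps (stress, rest) per female patient, three (stress, rest,
prone) per male patient, with per-class sex mixes of 39F/10M (normal
patients) and 313F/91M (abnormal). The phase and sex attributes exist to
reproduce archive-style summary tables and leakage bookkeeping; the features
never see them, and a test asserts that.

Every abnormal map carries its ground-truth defect parameters as an
attribute, so tests can verify defect geometry by direct summation (e.g. a
full-severity 90° sector removes exactly the sector-mask sum).

What the generator does **not** emulate: SPECT physics (attenuation, Poisson
counting, reconstruction artefacts), the radial structure of real perfusion
territories, colour-table rendering, or correlations between a patient's
stress and rest maps. Consequently, a model's performance on this synthetic
regime says that the *pipeline* is correct and well-calibrated — counts,
partitions, leakage-freedom, metric arithmetic, model contracts — not that
the features would achieve any particular accuracy on clinical images, where
the test-set metrics are expected to be substantially lower.

## Rotation augmentation

Normal maps are the minority class (about 10.7% of the default archive).
Each training partition is therefore expanded with `copiesPerImage = 3`
rotated copies of each of its normal maps, raising the normal share of the
training rows to roughly 32%. Two design points matter:

* **Angles.** The default angles are 90°, 180° and 270°: on a square grid
  these are exact index permutations — lossless, interpolation-free, and
  mass-conserving to the pixel. Arbitrary angles (e.g. ±10°) are available
  via `augmentationConfig(angles = ...)` with bilinear or nearest-neighbour
  resampling (delegated to `EBImage::rotate()`); on a centred disc these
  conserve total intensity to well under 2%, which the tests check. Exact
  quarter turns were chosen as the default because they make the
  augmentation reproducible to the bit and keep the feature permutation
  properties exact.
* **Order of operations.** Augmentation operates on *images*, and features
  are re-extracted afterwards, per fold. Rotation changes band sums, so
  duplicating feature rows instead would be both incorrect and useless.

Abnormal maps are never augmented, and a count law (`copies × n_normal`
outputs, all labelled normal) is asserted property-style.

## Cross-validation without leakage

`runCV()` assigns only `provenance = "acquired"` maps to folds. Folds are
stratified: within each class, samples are dealt as evenly as possible, and
remainder samples go to the folds with the smallest running totals, so both
the per-fold class counts and the total fold sizes differ by at most one.
Stratification is not optional at 10.7% prevalence — unstratified folds
would risk test partitions with no normal map at all, leaving AUC undefined.

Within each fold, the pipeline is: split first, augment the training
normals, extract features from the combined training maps, train, and test
on the held-out *acquired* maps only. Because augmentation happens after the
split, no rotated copy of a test image can reach the training set; the run
asserts this (`sourceMapId` intersection with the test partition must be
empty) and records the audit per fold in the report. Folds are per image,
not per patient: with multiple maps per patient, two maps of one patient can
land in different folds. A patient-grouped mode would be a natural
extension; it is deliberately out of scope here, and the per-image
convention is stated rather than hidden.

## Models and metrics

Four ensemble families share a single contract (`trainModel()`,
`predictScores()` in [0, 1], `predictLabels()` with ties at the threshold
going to the positive class):

* **Random forest** — bagged, fully grown trees (`randomForest`, `ntree =
  500`, `nodesize = 1`). On training rows that are unique and
  non-contradictory, resubstitution accuracy reaches 1.0: every tree that
  saw a row in-bag classifies it perfectly, and in-bag trees are the
  majority (≈63%) for every row.
* **Extreme gradient boosting** — `xgboost` with its standard defaults
  (100 rounds, η 0.3, depth 6), single-threaded for determinism.
* **Adaptive boosting** — weighted decision stumps (`rpart`, depth 1) with
  multiplicative reweighting of misclassified samples and
  `log((1 - err)/err)` stage weights; the score is the weighted vote share.
* **Gradient boosting** — stagewise `rpart` regression trees (depth 3) fit
  to the binomial-deviance gradient, with a Newton step per leaf
  (`sum(residual) / sum(p(1 - p))`) and learning rate 0.1.

Adaptive and gradient boosting are implemented in the package on top of
`rpart` base learners; random forest and extreme gradient boosting delegate
to their reference implementations. All four are deterministic given the
spec seed, which the tests assert, and the effective hyperparameters are
embedded in every report.

The **positive class is abnormal (label 0)** for precision, sensitivity and
AUC — the clinically relevant finding, and the only orientation under which
precision and sensitivity near 0.96 are arithmetically possible at ~89%
abnormal prevalence. It is configurable (`pipelineConfig(positiveClass =
1)`) for the opposite reading.

Metric conventions, chosen where more than one convention exists:

* **AUC** is the rank statistic (probability a random positive outscores a
  random negative) with midrank tie handling — equivalent to the
  trapezoidal ROC area; tested against a brute-force all-pairs oracle.
* **Across-fold SD** uses the sample (n−1) estimator by default,
  configurable to population; a single-fold aggregate reports SD 0 with a
  warning.
* **Undefined metrics** (zero denominators, e.g. precision with nothing
  predicted positive) are reported as `NA` with a warning, never silently
  coerced to 0, so degenerate folds cannot quietly distort an average.
* Training-partition metrics are reported twice, flagged: on the augmented
  training matrix the model was actually fitted to (`train`) and on the
  acquired training rows only (`train_unaugmented`), since either could be
  meant by a "training set" panel.

## Problem sizes and calibration checks

The package's own acceptance checks run the full pipeline at the emulated
archive scale — 1,007 maps, 10 folds, with the random forest — which takes
well under a minute on one CPU; the remaining checks are property-based on
small random images. Two calibration results are worth stating because the
tests compute them:

* On the default synthetic archive, the random forest's mean
  training-partition accuracy across folds is exactly 1.000 (the saturation
  argument above), and the leakage audit finds zero augmented training maps
  derived from test images.
* On label-independent noise features, the mean test AUC across 10 folds is
  0.5 within Monte-Carlo error (±0.1 at 30 test samples per fold) — the
  pipeline does not manufacture signal.

## Known limitations

* Synthetic maps are a geometric idealisation; results on them bound
  pipeline correctness, not clinical performance.
* Folding is per image, not per patient (see above).
* Free-angle rotation introduces resampling error at the disc edge; the
  default quarter-turn angles avoid it entirely.
* No hyperparameter search, probability calibration, or feature-importance
  analysis: the four families run at documented defaults unless overridden.

## A small worked run

```{r example, eval = FALSE}
pms <- simulatePolarMaps(20, 60, polarMapConfig(), seed = 1)
cfg <- pipelineConfig(k = 5, seed = 2, models = list(
    modelSpec("random_forest", seed = 3),
    modelSpec("extreme_gradient_boosting", seed = 3)))
report <- runCV(pms, cfg)
report                      # prints the test-partition mean +/- sd table
leakageAudit(report)        # per-fold counts and the leakage verdict
formatReportTable(report, partition = "train")
```
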