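---
title: "Methods: global radiomic features and the gist signal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: global radiomic features and the gist signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammogist)
```

## The question and the design

The gist signal is a radiologist's rapid (~half-second) holistic
impression of a mammogram's abnormality, reported as a 0–100 score. It is
a *global* signal: it survives on images with no localizable lesion, which
suggests it is carried by whole-image texture rather than focal findings.
This package implements the corresponding analysis: reduce each
craniocaudal mammogram to 130 global radiomic features (GRFs), split the
image pool into strong-gist and weak-gist extremes by the quartiles of the
averaged observer score, and ask (a) whether a classifier can tell the two
extremes apart within each image category, and (b) which features carry
the signal.

Per-category modeling matters because category (normal, cancer-bearing,
various grades of prior mammograms of later-diagnosed women) is itself
correlated with gist. Fitting one classifier inside each category controls
for the category signal: if GRFs separate high from low gist *within*
normals, the model is not merely re-detecting cancer.

## Gist labeling

Each image's 13 observer scores are averaged; averaging is the intended
noise-suppression step, since individual gist responses are noisy but
consistent across expert observers. Labels are then assigned **rank-based
on the full pool**: the top `ceiling(n/4)` averaged scores are `high`, the
bottom `ceiling(n/4)` are `low`, the middle half is `excluded` but
retained in the label table. Two details are deliberate:

* *Rank-based rather than interpolated percentiles.* On a pool of 4191
  distinct scores this produces exactly 1048 high and 1048 low images — an
  exactly balanced extreme-group design, which value-interpolated
  percentile cuts cannot guarantee under ties.
* *Pool-level, not per-category, quartiles.* Categories are subset after
  the split, which is why per-category class counts are unbalanced (a
  category whose images mostly evoke strong gist contributes mostly highs).
* Ties at either cut are broken by ascending image id, so the labeling is
  a deterministic function of the score table.

## The 130-feature descriptor

Features are computed over the eroded breast interior only. The
preprocessing chain is: threshold at gray level 100 (a pixel is breast iff
its value is `>= 100`; the inequality direction is our reading of
"thresholding at 100" that keeps the threshold value inside the breast),
mirror right-breast images so all chest walls are on the left, crop to the
mask bounding box per image, then erode with a Euclidean disk,
`dx^2 + dy^2 <= r^2`. Out-of-bounds counts as background, so erosion also
retreats from image borders, including the chest-wall edge; this removes a
border strip but matches the purpose of excluding every vendor-processed
margin. Erosion is implemented by an exact Euclidean distance transform
(a pixel survives iff its squared distance to the nearest background pixel
exceeds `r^2`; squared inter-pixel distances are integers, so the test is
exact) and verified against the brute-force definition in the test suite.
The disk radius is 100 px at full clinical resolution (~2800 rows) and is
scaled proportionally (`round(100 * rows / 2800)`) for smaller images.

**GLCM block (110 features).** ROI intensities are quantized by min–max
linear binning into `N_g = 8` levels (the level count is a free choice:
8 keeps small test ROIs populated and is a common default in radiomics
toolchains; it is configurable). One co-occurrence matrix is built per
pixel distance `d` in {1, 3, 5, 9, 11}, accumulating the four standard
angles (0°, 45°, 90°, 135°) and counting each pair in both directions
(symmetric convention; configurable). Pairs are counted only when both
pixels are inside the ROI. Each matrix yields the 22-statistic formulary,
giving names like `Cluster_shade_9`. Two conventions deserve note:

* The paired *correlation* variants are `Correlation_m = (Σij·p − μxμy)/(σxσy)`
  and `Correlation_p = Σ(i−μx)(j−μy)p/(σxσy)` — algebraically identical,
  kept separate because the feature inventory lists both; the paired
  *homogeneity* variants are `Σp/(1+|i−j|)` and `Σp/(1+(i−j)²)`.
* Degenerate matrices stay finite: when `σx·σy = 0` both correlations are
  defined as 0; entropies use `0·log 0 = 0` (natural log by default,
  base-2 available); the information-measure radicand is clamped at 0.

**FOS block (20 features).** First-order statistics of the *raw*
(unquantized) ROI intensities: mean; standard deviation (`n−1`
denominator); moment skewness and non-excess kurtosis (both defined as 0
for a constant ROI); min and max; percentiles 5–95 and the median
(type-7 linear interpolation); and three ranges, `max−min`, `P95−P5`,
`P99−P1`. Because FOS features depend only on the intensity multiset,
they are invariant under mirroring — a property the tests exploit.

Every GLCM and FOS statistic, the GLCM matrix itself, the erosion, and
the AUC are each checked against an independently coded brute-force
implementation to within 1e-10 on at least 100 random small instances.

## Classification and evaluation

Each category dataset is evaluated with stratified 10-fold
cross-validation of a bagged ensemble of 500 decision trees
(`randomForest` with its defaults beyond `ntree`). Stratification is a
deliberate strengthening of plain random folding: with class ratios as
extreme as 545/71, unstratified folds can lose the minority class
entirely. The minority class is oversampled (resampling with replacement
up to equality) *inside each training fold only* — oversampling before
splitting would leak duplicated images across fold boundaries and inflate
the AUC, so the no-leakage variant is implemented. Each image is scored
exactly once, out of fold; the pooled scores give a rank-based
(Mann–Whitney) AUC, ties counted 1/2. The 95% CI is a stratified
bootstrap percentile interval (2000 resamples by default) over the scored
images; the CI method is a package choice, since only the interval itself
is conventionally reported. Importance is the per-feature mean decrease in
node impurity averaged over folds (permutation importance, clamped at
zero, is available by flag). Categories whose minority class is smaller
than the fold count are reported as skipped rather than fitted.

## Scree selection

The "important" features of a model are found by an elbow rule on the
sorted importance profile: sort descending (ties broken by canonical
feature order), take the 129 consecutive gaps, cut at the **first
occurrence of the largest gap**. The rule is deterministic,
parameter-free, and invariant to shifting or positively rescaling the
scores; an all-equal profile selects everything. Applied to the published
per-model importance table shipped in `inst/extdata/` (130 features × 8
models, transcribed from the original study's report), it reproduces the
published selection counts for six of the eight models — All (7),
Normal (7), Cancer (8), Prior-Visible (7), Prior-1 (6), Prior-2 (6). For
the remaining two models (Missed, Prior-Invisible) the published counts
came from visual inspection of scree charts and no simple gap rule on the
rounded printed scores recovers them (the rule yields 15 and 2); these
two are documented divergences, not tuned around. Selected features are
grouped into families by stripping the distance suffix and merging the
three range statistics; the published flagged features group into exactly
five families: cluster shade, standard deviation, skewness, kurtosis,
range.

## The synthetic cohort

The original mammograms are not public, so the package generates a
cohort with the statistical structure the analysis assumes. Design
constants follow the study: 13 observers, 0–100 scores, eight categories.
Per image:

* **Geometry.** A half-elliptical "breast" anchored at the chest-wall
  edge (left for `L`, right for `R`), on a background at gray level 40
  (safely below the threshold of 100) with mild noise clipped to stay
  below 100. Foreground pixels are kept in [100, 255], so thresholding
  recovers the geometry exactly.
* **Texture.** Spatially correlated Gaussian noise (separable 5-pixel
  box smoothing of white noise), standardized, then passed through an
  asymmetric quadratic warp `z + c(z² − 1)/2` and a smooth bounding
  squash `1.6·tanh(w/1.6)`, and finally scaled and shifted into intensity
  units. The warp coefficient `c` carries the planted cluster-shade and
  skewness effects; the intensity scale carries the planted spread
  effect (`+30` gray levels at latent gist 100, scaled by
  `latent_gist/100`). Because the squash bounds the field *before* the
  spread is applied, the spread acts as a pure linear scale on the
  histogram and min–max quantization cancels it for the GLCM features —
  the knobs stay interpretable and largely decoupled. Per-image nuisance
  draws (brightness `N(177, 8)`, base texture scale `max(6, N(12, 1.5))`,
  warp jitter `N(0, 0.05)`) make non-planted features noisy across
  images, as real breasts vary in brightness and parenchymal texture
  independently of gist.
* **Latent gist and scores.** Latent gist is drawn from a two-component
  truncated-Gaussian mixture (means 25 and 75, sd 10, truncated to
  [0, 100]) whose weight on the high component is category-specific,
  emulating the observed asymmetry of extreme-quartile membership (e.g.
  0.88 for cancer images, 0.25 for normals). Observer scores are
  `clip(latent + N(0, 10), 0, 100)` — clipping, not resampling, as the
  simplest model of a bounded slider. The averaged-score distribution is
  a stand-in, not an estimate: the original score distribution was never
  reported.

What the generator does **not** emulate: photorealistic parenchymal
patterns, vendor post-processing, pectoral muscle, observer expertise
differences, or intra-observer variability. Consequently, passing the
planted-recovery test shows that the pipeline recovers a known
texture–gist association at realistic sample sizes; it does not certify
the published effect sizes on clinical images, which are out of reach
without the original data.

## Problem sizes and reproducibility

The test suite and the acceptance script use a 400-image cohort at
128×96 pixels for the end-to-end planted-recovery run (the "All" model
then has 100 high and 100 low images, 10-fold CV, 500 trees, plus 10
permutation-null repetitions), 256×256 images for single-image feature
checks, and ≥100 random small instances per brute-force oracle. These
sizes give stable statistics while keeping a full run in the
one-minute range on a single CPU. All randomness flows from explicit
seeds: the pipeline fans its global seed out to the cohort and to each
per-category model through a fixed affine derivation, so a run is
reproducible bit for bit from its echoed config (stored as JSON; the
validated constructor `pipeline_config()` plays the role of a config
schema).

## Known limitations

* The GLCM variant pairs (`_m`/`_p`, homogeneity) follow the canonical
  22-statistic formulary; the original study cites but does not print its
  formulas, so line-by-line agreement cannot be verified.
* The quantization level count and symmetry convention of the original
  analysis are unreported; both are configurable here, with defaults
  stated above.
* The scree rule is one formalization of a visual judgment; two of the
  eight published selection counts are not reproducible by any simple
  gap rule on the rounded published scores.
* Synthetic AUCs near 1.0 reflect the planted effect sizes, not clinical
  difficulty; the permutation null (mean AUC ≈ 0.5) is the calibration
  check.
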