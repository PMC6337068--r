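---
title: "Methods: interpretable glioma grading from H&E tiles and Ki-67"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interpretable glioma grading from H&E tiles and Ki-67}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`gliograde` implements an automated, interpretable grading platform for
diffuse gliomas of WHO grades II, III and IV. Its inputs are
haematoxylin-and-eosin (H&E) tile images and per-case Ki-67
immunohistochemistry counts; its outputs are a three-class grade
prediction per case, comparative performance of four classifier families,
and a per-case explanation of which features drove the decision. The
pipeline has six stages:

1. **ROI identification** — the slide is partitioned into fixed-size,
   non-overlapping tiles; nuclei are detected in every tile by watershed
   segmentation; the `k = 5` most cellular tiles become the regions of
   interest (ROIs). Because all tiles have equal area, ranking by raw
   nucleus count and ranking by density are identical; ties are broken in
   row-major order for determinism, and partial edge tiles are dropped
   rather than padded so no tile has a deflated count.
2. **Nucleus segmentation** — colour deconvolution into haematoxylin and
   eosin optical-density channels, Otsu thresholding of the haematoxylin
   channel, morphological opening, Euclidean distance transform, and
   watershed with seed maxima separated by at least
   `seed_min_distance_px`. Regions below `min_nucleus_area_px` are
   discarded and labels are renumbered contiguously.
3. **Feature extraction** — 24 *visual* features (nuclear morphology,
   staining, spatial pattern), 171 *sub-visual* features (first-order
   intensity statistics and grey-level co-occurrence matrix texture), and
   the Ki-67 proliferative index `PI = positive/total × 100`.
4. **Feature selection** — random-forest impurity importance with backward
   elimination, applied twice to the sub-visual features
   (171 → 50 → 15) and once to the visual features (24 → 11); Ki-67 is a
   fixed immunohistochemical covariate and is never eliminated. The model
   table therefore has 27 features.
5. **Grading** — four families (RBF-kernel SVM, random forest,
   gradient-boosted trees, single-hidden-layer neural network) are tuned
   by inner 5-fold stratified cross-validation and compared under 30
   repeats of a stratified 75%/25% hold-out, with identical splits across
   families so the comparison is paired. A 30-case external hold-out
   (stratified 10/9/11) is set aside before the repeated splits and scored
   by each repeat's model of the best family.
6. **Explanation** — a local surrogate in the LIME family: perturbation
   samples around the case in standardized feature space, proximity-kernel
   weights, feature screening by weighted correlation, and a weighted
   ridge regression of the model's class probability on the screened
   features, one surrogate per grade.

# The synthetic cohort

No clinical images ship with the package. The `synthetic_data` module
generates a cohort whose *statistical structure* mirrors a 146-case
grading study (49 grade II, 45 grade III, 52 grade IV): nuclear density,
size, pleomorphism (eccentricity spread), chromasia (stain darkness),
spatial clustering and the Ki-67 proliferative index all increase with
grade. The per-grade defaults are:

| grade | nuclei/tile | radius (px) | ecc max | darkness | cluster frac | Ki-67 PI (%) |
|-------|-------------|-------------|---------|----------|--------------|--------------|
| II    | 150         | 6 ± 1       | 0.3     | 0.50     | 0.1          | 3.0 ± 2.1    |
| III   | 300         | 7 ± 2       | 0.6     | 0.60     | 0.3          | 11.8 ± 3.4   |
| IV    | 450         | 8 ± 3       | 0.8     | 0.75     | 0.5          | 15.8 ± 7.4   |

The Ki-67 columns are the accepted clinical per-grade norms for gliomas;
the imaging columns are this package's own design, chosen once so grades
are learnable but overlapping (the III/IV Ki-67 distributions overlap
heavily, as they do clinically). Nucleus counts are Poisson per tile;
radii are normal truncated at 2.5 px; eccentricities are uniform on
`[0, ecc_max]`; a `cluster_fraction` of nuclei is placed around Poisson
cluster centres (SD 25 px) and the rest uniformly. Candidate positions
are re-drawn when a nucleus would overlap an accepted one by more than
roughly 30% of its area (centre distance below half the sum of semi-major
axes), which deliberately leaves touching nuclei for the watershed to
split; a zero-overlap mode with a hard boundary gap exists for oracle
tests. Ki-67 counting follows the clinical protocol: total cells uniform
on `[1000, 3000]` (at least 1000 cells are always examined), PI normal
truncated to `[0, 100]`, positives binomial. One PI is drawn per case,
not per ROI, because grading studies report a single Ki-67 value per
patient.

Rendering uses the Beer–Lambert law with the Ruifrok–Johnston H&E stain
vectors: nuclei are ellipses carrying haematoxylin concentration, the
background carries a smooth eosin field (0.15 OD baseline plus a
bilinearly-interpolated coarse Gaussian field, SD 0.05), and Gaussian
pixel noise (SD 2/255) is added before 8-bit quantization. Rendered
images therefore round-trip PNG files byte-identically, which is what
makes whole-cohort regeneration reproducible checksum-for-checksum.

**Scale.** The magnification of the emulated tiles is arbitrary — the
source protocol mixes 20×–40× scans and fixes only the tile pixel count.
Real slides are tiled at 5120 × 5120 px; desk-scale synthesis uses 512-px
tiles with all geometry scale-free, and the default synthetic slide is a
2 × 2 tile grid (1024² px). That keeps a full 146-case cohort build to
minutes on one CPU; with four tiles and `k = 5` every tile is retained as
an ROI at desk scale, and the top-k ranking proper is exercised by tests
on larger grids. Segmentation defaults (`min_nucleus_area_px = 40`,
`seed_min_distance_px = 7`, opening radius 1 px) are stated at the 512-px
scale and scale linearly with resolution.

**What the generator does not emulate:** necrosis, microvascular
proliferation, mitoses, staining artefacts, tissue folds, scanner colour
profiles, or intra-case heterogeneity beyond Poisson sampling. Passing
tests on this cohort demonstrates that the pipeline's machinery is
correct and that it recovers planted grade structure; it says nothing
about accuracy on clinical slides.

# Segmentation choices

The watershed detector is specified only by name in the grading
literature, so every parameter here is an explicit, config-exposed
default. Stain separation is true colour deconvolution — the inverse of
the 3×3 stain matrix applied to optical densities, with the residual
vector constructed as the cross product of the H and E vectors. Naive
projection of OD onto the H vector is *not* equivalent: the H and E
vectors have a dot product of ≈ 0.77, so projection leaks eosin signal
into the nuclear channel and faint nuclei drop below threshold.

Thresholding is Otsu on the haematoxylin channel with a floor of 0.15 OD
(`od_floor`); without the floor, Otsu thresholds pure background noise on
(near-)blank tiles and fabricates foreground. The watershed runs on the
negative Euclidean distance transform with seed maxima at least 7 px
apart — the choice that splits touching round nuclei, which is exactly
the failure mode the generator's overlap model produces. We segment the
deconvolved haematoxylin channel rather than grayscale because nuclear
chromatin is what haematoxylin stains.

Per-nucleus measurements use fixed, documented conventions so golden
values are stable: perimeter is the 4-direction Crofton estimator
(verified against an independent implementation on analytic shapes);
axes and eccentricity come from second central moments (with the 1/12
pixel-square correction); solidity rasterizes the convex hull of pixel
centres back onto the lattice, so convex regions score exactly 1;
circularity is `4πA/P²` and may slightly exceed 1 on small rasterized
disks. The perinuclear eosin ring is the background within 2 px of a
nucleus, assigned to its nearest nucleus by Voronoi propagation of the
label image.

# The feature battery

The battery's total sizes (24 visual, 171 sub-visual, 1 Ki-67) are fixed
by design; the decomposition is this package's canonical reconstruction,
chosen to (a) sum exactly to those counts and (b) include every feature
that appears by name in per-case explanations (SD of perimeter, SD of
major axis, nuclei count, spatial pattern, GLCM texture):

* **Visual (24)** = 7 morphology measures (area, perimeter, major axis,
  minor axis, circularity, eccentricity, solidity) × {mean, SD} over all
  nuclei pooled across the selected ROIs (14), plus 5 staining features
  (mean haematoxylin OD, mean within-nucleus intensity SD, mean
  perinuclear eosin OD, nucleus-to-background contrast, chromatin
  entropy), plus 5 pattern features (nuclei count, density per px²,
  mean and SD of nearest-neighbour distance, Clark–Evans index; computed
  per ROI and averaged).
* **Sub-visual (171)** = 13 first-order statistics × 3 channels
  (grayscale, haematoxylin OD, eosin OD) = 39, plus 11 GLCM properties ×
  4 angles (0°, 45°, 90°, 135°) × 3 distances (1, 2, 4 px) = 132,
  computed on the full ROI tile and averaged across the k ROIs so each
  patient contributes one vector.

GLCM details: the grayscale is quantized to 32 levels over the fixed
0–255 range (so an intensity shift by a whole bin leaves texture
unchanged); matrices are symmetrized and normalized; "energy" is the
angular second moment ΣP²; the correlation of a constant image is defined
as 1; first-order entropy uses a 64-bin histogram over the observed
range; skewness and excess kurtosis of a zero-variance channel are
defined as 0 so the feature table never contains missing values. Ki-67
enters the model table in percent (the display scale of the index
itself); because every model standardizes features on the training rows,
the percent-vs-fraction choice does not affect any fit.

# Feature selection

`rank_importance` is mean decrease in Gini impurity from a 500-tree
forest, normalized to sum to 1. `backward_eliminate` drops the least
important `ceil(0.2 × current)` features per round — capped so the count
never falls below the target, since an overshoot could not be trimmed
back up — and records stratified CV accuracy per round. "Applied twice"
to the sub-visual features is realized as two sequential elimination
stages with a config-exposed intermediate size of 50, a value the source
design leaves open. The visual features use the same procedure (also left
unstated in the source; we saw no reason to treat them differently), and
Ki-67 is exempt by design: it is an IHC measurement, not an image feature
competing for selection.

# Grading harness

Defaults: SVM cost ∈ {0.1, 1, 10, 100} × gamma ∈ {scale, 0.01, 0.1}
(RBF; "scale" = 1/(p·Var(X)) on the standardized training matrix); RF
trees ∈ {200, 500} × depth ∈ {∞, 10} (depth mapped to
`maxnodes = min(2^depth, n)`); GBDT learning rate ∈ {0.05, 0.1} × rounds
∈ {100, 300} at depth 3; NN hidden size ∈ {16, 64} × weight decay
∈ {1e-4, 1e-2}. Small, honest grids — tuning is part of the procedure,
not a claim about optimal hyperparameters. Standardization statistics and
all tuning decisions come from training rows only (a canary test verifies
that shifting would-be test rows cannot change the fitted scaler). SVM
class probabilities use pairwise-coupling calibration; on degenerate
training sets too small to calibrate, prediction falls back to a one-hot
encoding of the predicted class.

"Per-grade accuracy" is class-conditional recall (the confusion matrix
row normalized by the true class count); macro averages are reported
alongside weighted ones because the source is silent on the averaging
convention. Repeated hold-out (not k-fold) matches the stated validation
design; per-class train counts use `round(0.75·n_c)`, which reproduces
the documented 116 → 87/29 arithmetic. The external-validation procedure
is ambiguous in the source ("30 cases … 30 times of cross-validation");
we score the 30 held-out cases with each of the 30 repeat-trained models
of the best family and report mean ± SD.

# Explanation engine

The explainer is written from scratch in the LIME family, with two
documented divergences from the canonical implementation: screening by
weighted correlation followed by weighted ridge (penalty 1.0, intercept
free) instead of a LASSO path — deterministic and dependency-light — and
Gaussian perturbations in standardized space rather than binarized
features, which matches a tabular, fully numeric battery. Kernel width is
the classic `σ = 0.75·√p`. The surrogate target is the one-vs-rest class
probability, not the discrete label, because probabilities carry the
local gradient information a linear surrogate can recover. The case
itself is sample 1 with weight 1. Zero-variance features are frozen at
the case value with a warning.

Reports distinguish the surrogate *coefficient* (the local effect
direction of a feature) from the *contribution* `coef × standardized
case value` — a low-Ki-67 grade II case is "supported by Ki-67" because a
negative coefficient times a negative standardized value is positive. The
key correctness property is linear-oracle equivalence: on a known linear
model the surrogate recovers the coefficients with cosine similarity
≥ 0.98 at n = 20,000 samples (it is exact up to ridge shrinkage).

# Numerical and reproducibility choices

* Every stochastic operation derives its stream from a master seed by
  fixed arithmetic (`master_seed + case index`, stage-specific offsets);
  RNG state is saved and restored around each seeded block, so library
  calls cannot desynchronize unrelated stages.
* Tie-breaks are deterministic everywhere (row-major for tiles, first
  maximum for grid cells).
* Degenerate inputs have defined behaviour: blank tiles segment to zero
  nuclei; an empty cohort writes an empty manifest; fewer than two nuclei
  per case is a hard error with guidance; `k` larger than the tile count
  selects all tiles and logs the shortfall; empty CV folds (tiny classes)
  are skipped.
* The pipeline caches each stage keyed on the md5 of its configuration
  subsection and inputs, so re-running a finished directory is a no-op
  and deterministic stages reproduce identical checksums.

# Problem sizes used by the test suite

Unit tests run on small profiles (tiles of 128–256 px, tens of nuclei)
chosen to exercise every code path in seconds. The acceptance-style
checks run the study-scale conditions: the full 146-case default cohort
through the complete pipeline (SVM family), 10,000 Ki-67 draws per grade,
100 segmentation-oracle tiles, 100 selection-recovery simulations at
5 informative / 45 noise features, and 20,000-sample surrogate fits.

# Known limitations

* The synthetic cohort's grade separation is planted; reported synthetic
  accuracies characterize the pipeline, not clinical performance.
* Impurity-based importance is biased toward correlated feature groups;
  duplicated (perfectly correlated) features *increase* their combined
  importance share rather than conserving it, which is a property of the
  estimator, not a bug (see the selection tests).
* Watershed under-segments heavily overlapping nuclei at grade IV
  densities; counts remain monotone in grade, which is what the ROI
  ranking and density features rely on.
* No tissue-vs-glass masking, no multiresolution pyramids, no vendor WSI
  readers: real-slide inputs must already be RGB rasters.
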