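# gliograde

Interpretable machine-learning grading of diffuse gliomas (WHO grades II,
III, IV) from H&E tile images and Ki-67 immunohistochemistry counts.

## The problem

Histopathological glioma grading drives treatment choice, but manual
grading is subjective and inter-observer agreement is imperfect. This
package implements an automated grading platform that mirrors how a
pathologist works — find the most cellular regions, quantify nuclear
morphology, staining and texture, fold in the Ki-67 proliferative index —
and then, unlike a black box, explains each case's grade call feature by
feature. It is aimed at computational-pathology researchers who want a
tested, fully reproducible reference pipeline.

The pipeline:

1. **ROI identification** — partition the slide into fixed-size tiles
   (5120 px for real slides, 512 px at desk scale), detect nuclei per tile
   by watershed, keep the `k = 5` most cellular tiles.
2. **Nucleus segmentation** — colour deconvolution (Beer–Lambert optical
   densities unmixed with the Ruifrok–Johnston H&E stain matrix), Otsu
   threshold on the haematoxylin channel, morphological opening, distance
   transform, marker-controlled watershed, area filter.
3. **Feature extraction** — per case: 24 visual features (nuclear
   morphology mean/SD, staining, spatial pattern), 171 sub-visual features
   (13 first-order statistics × 3 channels + 11 GLCM properties × 4 angles
   × 3 distances), and the Ki-67 proliferative index
   `PI = positive cells / total cells × 100`.
4. **Feature selection** — random-forest importance with backward
   elimination: sub-visual 171 → 50 → 15 (two stages), visual 24 → 11;
   Ki-67 is always retained → a 27-feature model table.
5. **Grading** — SVM (RBF), random forest, gradient-boosted trees and a
   neural network, each grid-tuned with inner 5-fold CV, compared under 30
   repeats of a stratified 75/25 hold-out with paired splits, plus a
   30-case external hold-out.
6. **Explanation** — a LIME-style local surrogate per case and grade:
   Gaussian perturbations in standardized feature space, proximity kernel
   `exp(-d²/σ²)` with `σ = 0.75√p`, weighted-correlation screening, and
   weighted ridge regression on the model's class probability.

Because no clinical images are distributed, the package ships a synthetic
cohort generator that emulates the statistical structure of a 146-case
study population (49 grade II / 45 grade III / 52 grade IV) with
grade-dependent nuclear density, size, pleomorphism, chromasia, spatial
clustering, and Ki-67 distributions (3.0 ± 2.1 %, 11.8 ± 3.4 %,
15.8 ± 7.4 % for grades II/III/IV). Every stage of the pipeline is tested
against this generator's ground truth. See `vignettes/methods.Rmd` for the
full model description and design rationale.

## Worked example

Generate a small synthetic cohort, extract features, select the battery,
train and compare models, and explain one case:

```r
library(gliograde)

cfg <- default_pipeline_config(master_seed = 1)
cfg$cohort$n_per_grade <- c(II = 10, III = 10, IV = 10)
cfg$split$n_repeats <- 10L
cfg$split$external_holdout <- 6L
cfg$selection$cv_folds <- 0L
cfg$models <- c("SVM", "RF")

manifest <- run_pipeline(cfg, "demo_run")
cat(readLines("demo_run/report.md"), sep = "\n")
```

The run takes about five minutes on one CPU and the report begins:

```
# Glioma grading run report

## Model comparison (mean ± SD over repeats)

| model | F1 | accuracy | precision | recall |
|-------|----|----------|-----------|--------|
| SVM | 1.00 ± 0.00 | 1.00 ± 0.00 | 1.00 ± 0.00 | 1.00 ± 0.00 |
| RF | 1.00 ± 0.00 | 1.00 ± 0.00 | 1.00 ± 0.00 | 1.00 ± 0.00 |

## Per-grade accuracy (pooled over repeats)

- SVM: II = 1.00, III = 1.00, IV = 1.00
- RF: II = 1.00, III = 1.00, IV = 1.00
```

Reading it: each row aggregates 10 repeated 75/25 hold-out splits of the
24 development cases (6 were held out for external validation); per-grade
accuracy is class-conditional recall pooled over repeats. Accuracy is
perfect because the generator's grade effects (nuclear density 150/300/450
per tile, Ki-67 3.0/11.8/15.8 %) are strong and the cohort is clean — this
characterizes the pipeline's machinery, not clinical difficulty. The
explanation section names each representative case's top contributors:

```
- case_001_II: predicted II (p = 0.82); top contributors:
  fo_gray_kurtosis (+0.022), nuclear_density (+0.021), sd_nn_distance (+0.021)
- case_021_IV: predicted IV (p = 0.82); top contributors:
  fo_gray_variance (+0.022), mean_area (+0.021), mean_perimeter (+0.020)
```

A signed contribution is the local surrogate coefficient times the case's
standardized feature value — the grade IV call above rests on large,
high-variance nuclei, the grade II call on low density and regular
spacing. With many grade-correlated features the SVM spreads its decision
across the battery, so no single feature dominates; Ki-67 rises to the top
when a model leans on it (see the planted-effect explanation tests).

At full scale — the default 146-case cohort, 30 repeats — the pipeline
reaches mean SVM hold-out accuracy 1.00 on the synthetic cohort, and the
full run takes about 12 minutes on one CPU.

A thin CLI over the same functions is installed at
`inst/cli/gliograde.R` with subcommands
`simulate | roi | segment | features | select | train | explain | run`.

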