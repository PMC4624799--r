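# herniaquant

Quantitative CT morphometry of ventral hernias (VH) in R.

A ventral hernia is a protrusion of abdominal contents through a defect in
the anterior abdominal wall. Whether the defect can be closed primarily at
repair or needs a **mesh bridge** is a key surgical decision, and it
correlates with geometry that routine CT already contains. `herniaquant`
turns sparse manual anatomical labels on abdominal CT (wall contours every
~5 cm, a dense hernia label, point landmarks) into twenty per-subject
morphometrics and statistical models of the bridge-closure endpoint. It is
aimed at imaging researchers who want a tested, reproducible reference
implementation of this pipeline, validated end to end on synthetic phantoms
with analytic ground truth.

## What it computes

* **Wall surfaces** — outer/inner anterior wall height fields
  `y = f(x, z)` by 2-D thin-plate-spline interpolation (kernel
  `U(r) = r² log r`) of sparse axial + sagittal contour labels; a closed
  abdominal-cavity surface; wall thickness along outer-surface normals.
* **Segmentation** — body extraction and fat/muscle separation by
  deterministic fuzzy C-means intensity clustering (m = 2); visceral vs
  subcutaneous fat split by the closed cavity surface.
* **Metrics A–T** — hernia volume, L-R/A-P/C-C diameters,
  anterior/posterior surface areas, mean A-P thickness (A–G); normalized
  location relative to the ASIS/xiphoid frame and landmark distances (H–L);
  body volume, cavity volume, hernia/cavity ratio, wall thickness mean/SD,
  fat volumes, evaluated height (M–T).
* **Reliability** — symmetric mean surface distance (MSD) and Hausdorff
  distance (HD) per wall structure, landmark Euclidean distances with
  per-landmark representative-point rules, Cohen's kappa on hernia masks.
* **Outcome models** — pooled-variance one-tailed t-tests; elastic-net
  regularized logistic regression minimizing

  ```
  (1/N) Deviance(β₀, β) + λ [ (1−α)/2 ‖β‖₂² + α ‖β‖₁ ]
  ```

  by IRLS + cyclic coordinate descent, with λ chosen by the
  one-standard-error cross-validation rule; a leave-one-out α sweep with
  false-prediction and retained-variable curves; and a linear soft-margin
  SVM separating hyperplane for the two retained metrics.
* **Synthetic data** — labeled CT phantoms (elliptic-cylinder torso,
  half-ellipsoid hernia cap, CT-like intensities) with closed-form ground
  truth, rater-noise perturbation, and calibrated 9-vs-17 synthetic cohorts
  with optional known generating coefficients.

## Worked example

```r
library(herniaquant)

spec <- phantom_spec(
  torso_semiaxes = c(120, 95), height = 300, spacing = c(2.5, 2.5, 5),
  subcut_thickness = 24, visceral_semiaxes = c(45, 28),
  label_z_range = c(25, 275),
  hernia = list(center_x = 0, center_z = 150,
                semiaxes = c(45, 25, 60), depth = 6),
  seed = 7)
ph <- make_phantom(spec)
ph$ground_truth$hernia_volume_cm3   # analytic: 141.4 cm^3 = (2/3)*pi*4.5*2.5*6
mv <- derive_all(ph$volume)
print(mv)
```

```
metric_vector (A-T):
  A Hernia volume (cm3)                        132.594
  B Hernia L-R diameter (cm)                   9
  C Hernia A-P diameter (cm)                   2.5
  D Hernia C-C diameter (cm)                   12
  ...
  N Abdominal cavity volume (cm3)              3530.44
  O Ratio of hernia to abdominal cavity volume 0.0375573
  P Mean abdominal wall thickness (cm)         1.53684
  ...
  T Evaluated height of abdominal region (cm)  25
```

The derived hernia volume (132.6 cm³) sits ~6% below the analytic 141.4 cm³
purely from voxelization at 2.5×2.5×5 mm; at 1 mm voxels the error is under
1% (asserted in the acceptance tests). B/C/D match the cap's analytic
extents (9, 2.5, 12 cm) exactly, and the cavity volume is within 2% of the
Steiner-formula truth.

Reliability against a simulated second rater (2 mm contour noise, 3 mm
landmark noise):

```r
volB <- perturb_labels(ph$volume, surface_noise_mm = 2,
                       landmark_noise_mm = 3, seed = 21)
reliability_report(ph$volume, volB)
#>   wall structures (MSD / HD, mm):
#>     outer_wall_axial       1.30 /   5.59      # E|N(0,2)| = 1.60 mm
#>     ...
#>   hernia Cohen's kappa: 0.858
```

Outcome models on a calibrated 9-vs-17 synthetic cohort:

```r
co <- make_cohort(9, 17, seed = 1)
head(cohort_ttests(co)[order(cohort_ttests(co)$p), ], 3)
#>   metric        t            p direction
#> 5      E 4.346188 0.0001095096       A>B
#> 7      G 4.009653 0.0002571052       A>B
#> 2      B 3.773532 0.0004659603       A>B

fit <- exploratory_fit(co, alpha = 0.9, n_folds = 5, nlambda = 40, seed = 1)
#> elastic-net logistic model: alpha = 0.9, lambda = 0.2728, 7/20 nonzero

sv <- svm_hyperplane(cohort_features(co)[, c("B", "E")], cohort_outcome(co))
#> linear SVM hyperplane: w = (0.023304, 0.0022692), b = -0.8215
#>   3 misclassified (all in the bridge class), 10 support vectors

accuracy_from_counts(4, 26)   # 84.6 (%)
```

## Command line

```sh
Rscript inst/cli/herniaquant.R run config.json       # full pipeline
Rscript inst/cli/herniaquant.R derive img.nii.gz lab.nii.gz out.csv
Rscript inst/cli/herniaquant.R reliability labA.nii.gz labB.nii.gz out.json
Rscript inst/cli/herniaquant.R sweep cohort.csv out.json
```

## Documentation

The methods vignette (`vignettes/herniaquant-methods.Rmd`) documents the
models, the conventions chosen where the labeling protocol is silent
(surface-area face orientation, kappa region, t-test tail, λ path), what
the synthetic world does and does not emulate, and known limitations.
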