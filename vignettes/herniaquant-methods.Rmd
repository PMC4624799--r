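---
title: "Quantitative ventral-hernia CT morphometry: models and methods"
author: "herniaquant developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative ventral-hernia CT morphometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Ventral hernias (VH) — protrusions of abdominal contents through a defect in
the anterior abdominal wall — are usually evaluated pre-operatively on routine
CT, but the information is mostly used qualitatively. A clinically important
endpoint is whether the fascial defect can be closed primarily at repair or
whether a **mesh bridge** is required. `herniaquant` implements a quantitative
pipeline that turns sparse manual anatomical labels on CT into twenty
morphometrics describing the hernia's shape, its location relative to bony
landmarks, and the surrounding body habitus, and then relates those metrics to
the bridge-closure endpoint with regularized regression.

Because no public labeled clinical dataset accompanies this problem, the
package ships a first-class synthetic generator: labeled CT phantoms with
analytic ground truth, and synthetic patient cohorts with known
outcome-generating structure. Every stage of the pipeline is validated against
these closed-form oracles.

## Coordinate and label conventions

Patient axes are fixed as x = left-to-right (L-R), y = posterior-to-anterior
(A-P), z = inferior-to-superior (C-C). Voxel indices are 0-based, a voxel's
coordinate is its center, and masks are voxel sets. Label codes (an encoding
convention of this package — the labeling protocol names structures but no
integer codes) are registered once in `label_registry()`: wall contours
(axial outer/inner 1/2, posterior 3, sagittal outer/inner 4/5), fascial lines
(linea alba 6, linea semilunaris 7), the dense hernia label 8, and point
landmarks 10–14 (xiphoid, umbilicus, ASIS left/right, pubic symphysis).

NIfTI-1 I/O is implemented in-package (`read_nifti()` / `write_nifti()`)
because no NIfTI reader exists in the supported dependency set; it covers the
axis-aligned, scalar 3-D subset this pipeline uses.

## Wall surfaces by thin-plate splines

Raters label wall contours only on sparse axial slices (every ~5 cm) plus a
few sagittal slices; the full surfaces are recovered by interpolation. Each
anterior wall surface is modeled as a height field $y = f(x, z)$ fit by a 2-D
thin-plate spline with kernel $U(r) = r^2 \log r$ and an affine part, pooling
axial and sagittal contour points as control points. With regularization
$\lambda_{tps} = 0$ (the default — labels are treated as exact) the spline
interpolates all control values; the affine part reproduces planar data
exactly, which the tests assert to machine precision.

The closed cavity surface is assembled per axial level: the inner anterior
curve and the posterior curve are joined by straight chords across the small
lateral gaps that the rater leaves at the flanks (10 degrees by default in
the phantom), and the stack is capped flat at the lowest and highest labeled
slices. For a convex cross-section the chord closure loses well under 1% of
the area at a 10-degree gap. Cavity volume integrates the cross-section area
(shoelace formula on 160-vertex polygons) over z by the trapezoidal rule at a
4 mm step.

Wall thickness is sampled along **outer-surface normals** (not nearest
points), which is stable under shear between the two surfaces: from each
sample on the outer surface, a root search along the inward normal finds the
inner surface; negative-thickness samples (surface crossings) are excluded
with a warning. The lateral 12% of the footprint is trimmed because the
height field becomes steep there and normals exit the footprint.

## Body and fat segmentation

The body is extracted with 2-cluster fuzzy C-means (FCM) on intensity
(fuzziness m = 2, tolerance 1e-5, max 300 iterations, deterministic quantile
initialization — no seed sensitivity), thresholding the higher-mean cluster
at membership 0.5, keeping the largest 26-connected component (which discards
the scan table) and filling in-plane holes. Inside the body, bone (> +200 HU)
and air (< −500 HU) are excluded — both thresholds are package choices, and
configurable — and a second 2-cluster FCM separates fat (lower mode) from
muscle/soft tissue. Two degenerate-input guards are deliberate: an all-air
volume errors out (the upper cluster center still sits at air level), and a
body with a single intensity mode falls back to a fixed fat window (< −30 HU)
with a warning, so a uniform-muscle body yields an essentially empty fat mask
rather than an arbitrary FCM split of noise.

Fat is split into **visceral** (voxel centers inside the closed cavity
cross-section, tested per axial level with a point-in-polygon test) and
**subcutaneous** (outside the cavity, inside the body), restricted to the
labeled vertical range; the partition is exact by construction.

## The twenty metrics

Metrics A–G are hernia shape (volume; L-R/A-P/C-C bounding-box extents;
anterior/posterior surface areas; mean A-P chord length), H–L are location
relative to landmarks, and M–T describe the surrounding body over the labeled
vertical range T. Conventions that the underlying protocol leaves open were
fixed as follows:

* **E/F (anterior/posterior surface areas)**: exposed voxel faces with
  outward normal +y count toward E, −y toward F; faces with zero A-P normal
  component are excluded. The alternative (splitting x/z faces equally) is
  inconsistent with the defining worked example of a rectangular box, where
  both areas must equal the box's y-facing face area.
* **G**: mean A-P chord over occupied (x, z) columns, reported in cm (its
  printed unit of cm^2 elsewhere is treated as a typo; the printed magnitudes
  are length-scaled).
* **Location metrics** use the unweighted hernia-mask centroid. H is the
  projection fraction along the left-ASIS-to-right-ASIS segment and may leave
  [0, 1]; I is the fraction from the mean ASIS level to the xiphoid level and
  may be negative — matching observed clinical ranges.
* **O = A / N**, defined as 0 for hernia-free subjects; shape and location
  metrics are *absent* (NA), never zero, when no hernia is labeled.
* Whether wall regions crossing the hernia defect should be excluded from
  interpolation is unspecified upstream; this package excludes hernia-labeled
  voxels from wall control points, so the spline bridges across the defect.

## Reliability statistics

Between two labelings of the same scan the package computes the symmetric
mean surface distance and Hausdorff distance on labeled contour voxel centers
(no interpolation — raters label discrete slices), landmark Euclidean
distances using per-landmark representative-point rules (centroid for
xiphoid/linea alba/linea semilunaris; centermost labeled point for the
umbilicus; most superior point for the pubic symphysis; most anterior point
for each ASIS; ties broken most-superior then most-right), and Cohen's kappa
on the hernia masks. Kappa depends on the negative-class region, which the
protocol never defines; the default region is the bounding box of the union
mask dilated by 10 voxels — large enough to be stable, small enough not to
inflate kappa with empty background — and is configurable and logged.

## Outcome models

Group differences use an unpaired pooled-variance one-tailed t-test. The
default tail follows the observed mean difference (consistent with published
two-group tables where near-null metrics report p close to 0.5); note that
under the null this convention rejects at **twice** the nominal rate, so the
type-I calibration test fixes the tail a priori.

Prediction uses elastic-net regularized logistic regression,

$$\min_{\beta_0, \beta} \tfrac{1}{N}\,\mathrm{Deviance}(\beta_0, \beta)
  + \lambda\left[\tfrac{1-\alpha}{2}\lVert\beta\rVert_2^2
  + \alpha\lVert\beta\rVert_1\right],$$

with the deviance in the −2 log-likelihood convention (hence this package's
λ is exactly twice glmnet's for the same solution — verified against glmnet
in the tests), features standardized internally, the intercept unpenalized,
and coefficients reported on the original scale. The fitter is IRLS with
cyclic coordinate descent, active-set screening, warm-started λ paths (100
log-spaced values from λ_max down to 1e-4·λ_max by default), and a
step-halving safeguard that makes the recorded objective trace provably
non-increasing. λ is chosen by cross-validation with the one-standard-error
rule: the largest λ whose CV deviance is within one SE of the minimum. The
inner CV default is leave-one-out (appropriate at N ≈ 26); stratified k-fold
is available and is what the tests use for large sweeps, trading a little
selection noise for an order-of-magnitude speedup — the scaled-down settings
(5 inner folds, 30–40 λ values, coarse α grids) are used wherever the full
grid would break the test-time budget.

The LOOCV α sweep records, per α, the false-prediction count (probabilities
rounded at 0.5) and the retained-variable count of the full-data fit at the
1-SE λ. The exploratory full-data fit at α = 0.9 identifies the most
predictive metrics, and a linear soft-margin SVM (sequential minimal
optimization on the dual, maximal-violating-pair selection, C = 1 by default
— no value is prescribed upstream) supplies the two-metric separating
hyperplane with its geometric margin.

## What the synthetic world does and does not emulate

The phantom torso is an elliptic cylinder: skin ellipse, a constant-depth
subcutaneous fat layer, a muscular wall whose thickness varies sinusoidally
in z, a cavity containing a visceral-fat ellipse and a bone disc, and a
disconnected scan-table slab. The hernia is an outward half-ellipsoid cap
whose cut plane crosses the anterior wall, so its volume, extents and
centroid have closed forms ((2/3)πabc etc.). Intensities are Gaussian
(air −1000, fat −90, muscle +40, bone +700, table +300 HU, SD 15 — standard
CT levels; none are prescribed upstream). Default voxel spacing is
1×1×5 mm with a ~400 mm field of view and a 35 cm labeled range with axial
wall labels every 5 cm, matching the clinical acquisition envelope; tests use
coarser voxels and smaller torsos purely for speed, which is legitimate
because every comparison is against the phantom's *own* analytic ground
truth. All ground truth is computed from the continuous geometry (Steiner's
formula for offset-region areas, 1-D quadrature in z, and a fine quadrature
only over the hernia bounding box for skin/fat overlaps) — never from the
voxelization.

Deliberate non-realism: no organs, no partial-volume or CT physics (beam
hardening, kernels), no correlated metric structure in the cohort generator
(metrics are drawn independently per group), and rater noise that is
independent per contour point rather than spatially smooth. A green test
therefore establishes correctness of the *computations* under the stated
geometric and distributional world, not clinical performance.

Cohort calibration: per-metric group distributions are log-normal for
volumes/areas/diameters/distances (strictly positive, right-skewed) and
normal for normalized locations and the volume ratio. The published
two-group table reports only mean \[min, max\]; σ is set by matching the
range ratio to the (1/(n+1), n/(n+1)) quantile span at the table's group
sizes and μ so the distribution mean is exact ("range-matched SDs" — a
package choice, not a claim about the clinical distribution). The two source
tables disagree on visceral fat volume by a factor of ~60 (a likely unit
slip); the cohort profile follows the two-group table verbatim since it is
the calibration target, while the phantom generator targets the population
table's ranges.

## Numerical choices and edge cases

* TPS: duplicate control points are an error (singular system); coincident
  (x, z) columns from pooled views are merged by averaging y; control sets
  larger than 900 points are thinned deterministically.
* FCM is binned to 1 HU internally; its objective is non-increasing by
  construction and asserted in tests.
* The rater-noise recovery check expects MSD ≈ E|N(0, 2 mm)| = 1.6 mm;
  re-rasterization quantizes displaced contour points to the voxel grid, so
  the acceptance band is 1.6 ± 0.4 mm at 1.2 mm in-plane spacing, set a
  priori to cover quantization bias plus Monte-Carlo error.
* Complete separation at λ = 0 is flagged as non-convergence, not an error;
  degenerate single-class CV folds are reshuffled with a logged seed.
* All generators consume explicit seeds; a master pipeline seed fans out to
  per-stage child seeds so stages can be re-run in isolation.

## Known limitations

* The anterior wall must be single-valued in y over its footprint; extreme
  pendulous anatomies would violate the height-field representation.
* Kappa values are only comparable across runs that share the same region
  convention.
* The LOOCV sweep at the full 0.01 α step with LOO-inner selection is
  computationally heavy (it refits ~70k regularization paths); the packaged
  defaults expose it, but the validation suite runs coarser, documented
  settings.
* Phantom landmarks are placed at plausible but schematic positions; location
  metrics are validated against coordinate arithmetic, not anatomy.
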