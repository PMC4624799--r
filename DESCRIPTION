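Package: herniaquant
Title: Quantitative CT Morphometry of Ventral Hernias
Version: 0.1.0
Authors@R: person("herniaquant", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantitative characterization of ventral hernias from
    labeled abdominal CT volumes. Reconstructs outer and inner abdominal wall
    surfaces from sparse axial and sagittal contour labels by thin-plate
    spline interpolation, segments the body and fat compartments by fuzzy
    C-means intensity clustering, and derives twenty shape, location and
    body morphometrics per subject. Includes rater-reliability statistics
    (mean surface distance, Hausdorff distance, landmark Euclidean distance,
    Cohen's kappa), elastic-net regularized logistic regression with the
    one-standard-error lambda rule and leave-one-out cross-validation for
    predicting mesh bridge requirement, a linear support vector machine for
    two-metric separating hyperplanes, and a synthetic phantom and cohort
    generator with analytic ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mgcv,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmnet
Config/testthat/edition: 3
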