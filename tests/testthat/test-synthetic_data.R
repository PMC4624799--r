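test_that("ground truth matches closed forms and is seed-invariant", {
  sp <- small_spec(hernia = list(center_x = 0, center_z = 150,
                                 semiaxes = c(60, 30, 80), depth = 8))
  gt <- herniaquant:::phantom_ground_truth(sp)
  # half-ellipsoid cap: (2/3) pi abc
  expect_equal(gt$hernia_volume_cm3, (2 / 3) * pi * 6 * 3 * 8, tolerance = 1e-9)
  expect_equal(gt$hernia_extents_cm, c(12, 3, 16))
  expect_equal(gt$evaluated_height_cm, 25)
  # constant-offset cavity: Steiner formula integrated over z
  sp0 <- small_spec(wall_thickness_amp = 0)
  gt0 <- herniaquant:::phantom_ground_truth(sp0)
  a <- 120; b <- 95; d <- 24 + 14
  L <- herniaquant:::ellipse_perimeter(a, b)
  expect_equal(gt0$cavity_volume_cm3,
               (pi * a * b - d * L + pi * d^2) * 250 / 1e3, tolerance = 1e-6)
  gt_seed <- herniaquant:::phantom_ground_truth(small_spec(seed = 99L))
  expect_equal(gt_seed[names(gt_seed) != "landmarks_mm"],
               herniaquant:::phantom_ground_truth(small_spec(seed = 1L))[
                 names(gt_seed) != "landmarks_mm"])
})

test_that("phantom generation is deterministic and spec errors are caught", {
  ph1 <- make_phantom(small_spec(spacing = c(5, 5, 10)))
  ph2 <- make_phantom(small_spec(spacing = c(5, 5, 10)))
  expect_identical(ph1$volume$intensity, ph2$volume$intensity)
  expect_identical(ph1$volume$labels, ph2$volume$labels)
  # hernia cap that never crosses the wall is a spec error
  expect_error(small_spec(hernia = list(center_x = 0, center_z = 150,
                                        semiaxes = c(45, 25, 60), depth = 30)),
               "does not cross")
  expect_error(phantom_spec(axial_spacing = 2, spacing = c(1, 1, 5)),
               "slice thickness")
})

test_that("hernia-free phantoms carry no hernia label", {
  ph <- fx_nohernia_phantom()
  expect_equal(sum(ph$volume$labels == label_registry()[["hernia"]]), 0L)
  expect_equal(ph$ground_truth$hernia_volume_cm3, 0)
})

test_that("wall labels appear only on sparse slices; hernia label is dense", {
  ph <- fx_hernia_phantom()
  vol <- ph$volume
  reg <- label_registry()
  z_of <- function(code) {
    w <- which(vol$labels == code)
    sort(unique(arrayInd(w, dim(vol$labels))[, 3]))
  }
  z_ax <- z_of(reg[["outer_wall_axial"]])
  expect_lte(length(z_ax), 7L)          # 250 mm / 50 mm spacing
  expect_gte(min(diff(z_ax)) * vol$spacing[3], 40)
  z_h <- z_of(reg[["hernia"]])
  expect_equal(z_h, seq(min(z_h), max(z_h)))  # every slice it crosses
})

test_that("zero-noise perturbation is the identity", {
  ph <- fx_hernia_phantom()
  out <- perturb_labels(ph$volume, 0, 0, seed = 5L)
  expect_identical(out$labels, ph$volume$labels)
})

test_that("perturbation noise propagates at the expected scale", {
  # fine in-plane grid so rasterization quantization stays small vs 2 mm noise
  sp <- small_spec(spacing = c(1.2, 1.2, 5), hernia = NULL)
  ph <- make_phantom(sp)
  volB <- perturb_labels(ph$volume, surface_noise_mm = 2, landmark_noise_mm = 3,
                         seed = 21L)
  rep <- reliability_report(ph$volume, volB)
  msd_ax <- rep$wall$outer_wall_axial$msd
  # E|N(0, 2)| = 2 * sqrt(2/pi) ~= 1.60 mm, band includes quantization bias
  expect_gt(msd_ax, 1.1)
  expect_lt(msd_ax, 2.1)
  # landmark ED ~ |N3(0, 3^2 I)|, mean 3*sqrt(8/pi) ~= 4.8 mm; single draws
  # are chi-distributed so only a broad sanity band is asserted per landmark
  eds <- rep$landmarks[c("xiphoid", "asis_left", "asis_right", "pubic_symphysis")]
  expect_true(all(eds < 25))
  expect_gt(mean(eds), 0.5)
})

test_that("cohort calibration is unbiased for the bridge-group means", {
  prof <- vh_cohort_profile()
  reps <- 400L
  mA <- vapply(seq_len(reps), function(r) {
    co <- make_cohort(9, 17, seed = 1000L + r)
    mean(co$A[co$bridge == 1])
  }, 1)
  target <- prof["A", "mean_b"]
  expect_lt(abs(mean(mA) - target) / target, 0.15)
  # single-cohort sanity: right order of magnitude, strictly positive
  co <- make_cohort(9, 17, seed = 42L)
  expect_true(all(co$A > 0))
  expect_gt(mean(co$A[co$bridge == 1]), mean(co$A[co$bridge == 0]))
})

test_that("cohort generator validates inputs and supports logistic outcomes", {
  expect_error(make_cohort(1, 17), "group sizes")
  bad <- vh_cohort_profile()
  bad$max_b[1] <- bad$min_b[1]          # zero spread -> non-positive SD
  expect_error(make_cohort(9, 17, effect_profile = bad), "min < max")
  beta <- numeric(20); beta[c(2, 5)] <- c(2, -2)
  co <- make_cohort(60, 60, beta_true = beta, outcome_mode = "logistic",
                    seed = 9L)
  expect_true(all(co$bridge %in% 0:1))
  expect_true(all(table(co$bridge) > 10))
  expect_identical(make_cohort(9, 17, seed = 5L), make_cohort(9, 17, seed = 5L))
})

test_that("voxelized hernia volume converges to the analytic value", {
  # voxelize the default cap at 1 mm isotropic over its bounding box
  sp <- small_spec(hernia = list(center_x = 0, center_z = 150,
                                 semiaxes = c(60, 30, 80), depth = 8))
  fr <- herniaquant:::phantom_frame(sp)
  hx <- fr$cx; y_cut <- herniaquant:::skin_front_y(fr, hx) - 8
  xs <- seq(hx - 61, hx + 61, by = 1)
  ys <- seq(y_cut - 1, y_cut + 31, by = 1)
  zs <- seq(150 - 81, 150 + 81, by = 1)
  gg <- expand.grid(x = xs + 0.5, y = ys + 0.5, z = zs + 0.5)
  inh <- herniaquant:::hernia_inside(sp, fr, gg$x, gg$y, gg$z)
  vol_vox <- sum(inh) * 1e-3
  expect_lt(abs(vol_vox - (2 / 3) * pi * 6 * 3 * 8) / ((2 / 3) * pi * 6 * 3 * 8),
            0.01)
})
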