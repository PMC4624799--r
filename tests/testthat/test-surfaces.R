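test_that("TPS reproduces affine data exactly with zero warp", {
  set.seed(3)
  ctrl <- cbind(runif(30, -100, 100), runif(30, -100, 100))
  vals <- 2 * ctrl[, 1] - ctrl[, 2] + 5
  tps <- fit_tps(ctrl, vals)
  expect_lt(max(abs(tps$w)), 1e-8)
  grid <- cbind(runif(200, -90, 90), runif(200, -90, 90))
  expect_equal(predict(tps, grid), 2 * grid[, 1] - grid[, 2] + 5,
               tolerance = 1e-7)
  # side conditions: kernel weights orthogonal to the affine space
  expect_lt(abs(sum(tps$w)), 1e-8)
  expect_lt(max(abs(colSums(tps$w * ctrl))), 1e-5)
})

test_that("TPS interpolates control values at lambda = 0 and validates input", {
  set.seed(4)
  ctrl <- cbind(runif(40, 0, 200), runif(40, 0, 200))
  vals <- sin(ctrl[, 1] / 30) + cos(ctrl[, 2] / 40)
  tps <- fit_tps(ctrl, vals, lambda = 0)
  expect_equal(predict(tps, ctrl), vals, tolerance = 1e-8)
  # lambda > 0 smooths: no longer exact at controls
  tps_s <- fit_tps(ctrl, vals, lambda = 100)
  expect_gt(max(abs(predict(tps_s, ctrl) - vals)), 1e-4)
  expect_error(fit_tps(ctrl[1:3, ], vals[1:3]), "at least 4")
  expect_error(fit_tps(rbind(ctrl, ctrl[1, ]), c(vals, vals[1])), "duplicate")
})

test_that("TPS reconstructs a cylinder from slices spaced 5 cm", {
  # 50 control points: 5 slices x 10 points on y = sqrt(150^2 - x^2) over a
  # 110-degree anterior arc. (Steeper flank arcs increase the mid-slab
  # wiggle of the interpolant beyond 1 mm; the labeled anterior wall arc is
  # of this order.)
  r <- 150
  th <- seq(35, 145, length.out = 10) * pi / 180
  zs <- seq(0, 200, by = 50)
  ctrl <- do.call(rbind, lapply(zs, function(z) cbind(r * cos(th), z)))
  vals <- rep(r * sin(th), length(zs))
  tps <- fit_tps(ctrl, vals)
  # interpolation between slices: evaluate at the labeled x stations on the
  # unlabeled z levels (the in-slice sampling density is the rater's choice)
  ev_z <- seq(5, 195, by = 10)
  grid <- as.matrix(expand.grid(x = r * cos(th), z = ev_z))
  pred <- predict(tps, grid)
  truth <- sqrt(r^2 - grid[, 1]^2)
  expect_lt(max(abs(pred - truth)), 1)   # < 1 mm
})

test_that("interpolated cavity volume matches the elliptic-cylinder truth", {
  # analytic contours (no rasterization): constant wall -> Steiner closed form
  cs <- analytic_contours()
  surf <- interpolate_walls(cs)
  expect_true(herniaquant:::cavity_is_closed(surf))
  a <- 120; b <- 95; d <- 38
  L <- herniaquant:::ellipse_perimeter(a, b)
  truth <- (pi * a * b - d * L + pi * d^2) * 250 / 1e3
  expect_lt(abs(cavity_volume(surf) - truth) / truth, 0.02)
  # rasterized phantom route stays within 2% of its own ground truth
  ph <- fx_hernia_phantom()
  surf2 <- interpolate_walls(ph$volume)
  gt <- ph$ground_truth$cavity_volume_cm3
  expect_lt(abs(cavity_volume(surf2) - gt) / gt, 0.02)
})

test_that("dense contours reproduce the contour stack; sparse labeling is stable", {
  cs_dense <- analytic_contours(z_slices = seq(25, 275, by = 10))
  # default control thinning keeps the stack within ~1 mm ...
  surf <- interpolate_walls(cs_dense)
  pred <- predict(surf$inner, cs_dense$inner_anterior[, c(1, 3)])
  expect_lt(max(abs(pred - cs_dense$inner_anterior[, 2])), 1)
  # ... and without thinning the spline interpolates the stack exactly
  surf_full_ctrl <- interpolate_walls(cs_dense, max_control = 5000L)
  pred2 <- predict(surf_full_ctrl$inner, cs_dense$inner_anterior[, c(1, 3)])
  expect_lt(max(abs(pred2 - cs_dense$inner_anterior[, 2])), 1e-6)
  # halving the labeled slices moves cavity volume by < 3% (common z range)
  cs_half <- analytic_contours(z_slices = seq(25, 225, by = 100))
  zr <- c(25, 225)
  v_half <- cavity_volume(interpolate_walls(cs_half), z_range = zr)
  v_full <- cavity_volume(interpolate_walls(analytic_contours()), z_range = zr)
  expect_lt(abs(v_half - v_full) / v_full, 0.03)
})

test_that("surface error decreases as labeled-slice spacing shrinks", {
  t_fun <- function(z) 14 + 6 * sin(2 * pi * z / 150)
  err_at <- function(by) {
    cs <- analytic_contours(t_fun = t_fun, z_slices = seq(25, 275, by = by))
    surf <- interpolate_walls(cs)
    ev <- as.matrix(expand.grid(x = seq(100, 220, by = 10),
                                z = seq(30, 270, by = 5)))
    pred <- predict(surf$inner, ev)
    truth <- vapply(seq_len(nrow(ev)), function(i) {
      fr <- list(a = 120, b = 95, cx = 160, cy = 150)
      herniaquant:::offset_front_y(fr, ev[i, 1], 24 + t_fun(ev[i, 2]))
    }, 1)
    max(abs(pred - truth))
  }
  errs <- c(err_at(125), err_at(50), err_at(25))
  expect_true(all(diff(errs) < 0))
})

test_that("wall thickness recovers constant and sinusoidal offsets", {
  # concentric elliptic cylinders 12 mm apart
  cs <- analytic_contours(t_fun = function(z) rep(12, length(z)))
  th <- wall_thickness_stats(interpolate_walls(cs))
  expect_equal(th$mean_cm, 1.2, tolerance = 0.01)
  expect_lt(th$sd_cm, 0.02)
  # sinusoidal thickness 10..20 mm over full periods: mean 1.5 cm,
  # SD = amplitude / sqrt(2) = 0.354 cm
  t_fun <- function(z) 15 + 5 * sin(2 * pi * (z - 25) / 125)
  cs2 <- analytic_contours(t_fun = t_fun, z_slices = seq(25, 275, by = 25))
  th2 <- wall_thickness_stats(interpolate_walls(cs2), n_z = 40)
  expect_equal(th2$mean_cm, 1.5, tolerance = 0.1 * 1.5)
  expect_equal(th2$sd_cm, 0.5 / sqrt(2), tolerance = 0.1 * 0.5 / sqrt(2))
})

test_that("interpolate_walls enforces its preconditions", {
  cs <- analytic_contours(z_slices = c(100))
  expect_error(interpolate_walls(cs), ">= 2 slices")
  ph <- fx_hernia_phantom()
  expect_true(herniaquant:::cavity_is_closed(interpolate_walls(ph$volume)))
})
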