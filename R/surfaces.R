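# Thin-plate-spline reconstruction of abdominal wall surfaces from sparse
# labeled contours, cavity closure, and wall thickness statistics.
#
# Anterior wall surfaces are height fields y = f(x, z) fit by a 2-D TPS
# (kernel r^2 log r) with axial and sagittal contour points pooled as control
# points. The posterior wall is a second height field. The closed cavity
# surface is formed per axial level by joining the inner anterior and
# posterior curves with straight chords across the small lateral gaps and
# capping flat at the lowest/highest labeled slices.

tps_kernel <- function(r) {
  out <- r
  out[] <- 0
  nz <- r > 0
  out[nz] <- r[nz]^2 * log(r[nz])
  out
}

#' Fit a 2-D thin-plate spline
#'
#' Interpolates (or with `lambda > 0`, smooths) scalar values over control
#' points in the plane with the biharmonic kernel r^2 log r plus an affine
#' part. With `lambda = 0` the spline passes through all control values.
#'
#' @param control n x 2 matrix of control point coordinates (mm).
#' @param values scalar value per control point.
#' @param lambda regularization weight >= 0 (0 = pure interpolation).
#' @return object of class `tps` with fields `centers`, `w` (kernel
#'   weights, orthogonal to the affine space), `a` (affine coefficients
#'   a0 + a1 x + a2 z) and `lambda`.
#' @export
fit_tps <- function(control, values, lambda = 0) {
  control <- as.matrix(control)
  if (ncol(control) != 2L) stop_hq("control points must be n x 2")
  if (lambda < 0) stop_hq("lambda must be >= 0")
  n <- nrow(control)
  if (n < 4L)
    stop_hq("need at least 4 control points for a 2-D thin-plate spline")
  if (anyDuplicated(round(control, 9)))
    stop_hq("duplicate control points make the TPS system singular; de-duplicate first")
  if (length(values) != n) stop_hq("values must match control points")
  D <- as.matrix(stats::dist(control))
  K <- tps_kernel(D)
  if (lambda > 0) K <- K + diag(lambda, n)
  P <- cbind(1, control)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- c(values, 0, 0, 0)
  sol <- tryCatch(solve(A, rhs), error = function(e)
    stop_hq(sprintf("singular TPS system (%s); check control point geometry",
                    conditionMessage(e))))
  structure(list(centers = control, w = sol[1:n], a = sol[n + 1:3],
                 lambda = lambda), class = "tps")
}

#' Evaluate a fitted thin-plate spline
#' @param object a `tps` from [fit_tps()].
#' @param xy m x 2 matrix of evaluation coordinates.
#' @param ... unused.
#' @return numeric vector of length m.
#' @export
predict.tps <- function(object, xy, ...) {
  xy <- matrix(as.numeric(xy), ncol = 2L)
  out <- object$a[1] + xy %*% object$a[2:3]
  # chunk the kernel matrix to bound memory on large evaluation grids
  i <- 1L; m <- nrow(xy)
  while (i <= m) {
    j <- min(i + 4000L - 1L, m)
    d2 <- outer(rowSums(xy[i:j, , drop = FALSE]^2),
                rowSums(object$centers^2), "+") -
          2 * tcrossprod(xy[i:j, , drop = FALSE], object$centers)
    d <- sqrt(pmax(d2, 0))
    out[i:j] <- out[i:j] + tps_kernel(d) %*% object$w
    i <- j + 1L
  }
  as.vector(out)
}

# Extract wall contour points (mm) from a labeled volume, grouped by
# structure, together with per-axial-slice footprints.
contours_from_labels <- function(vol) {
  reg <- label_registry()
  get_pts <- function(code) label_points_mm(vol, reg[[code]])
  ax_out <- get_pts("outer_wall_axial")
  ax_in <- get_pts("inner_wall_axial")
  post <- get_pts("posterior_wall")
  sg_out <- get_pts("outer_wall_sagittal")
  sg_in <- get_pts("inner_wall_sagittal")
  slice_info <- function(p) {
    if (!nrow(p)) return(NULL)
    zs <- sort(unique(p[, 3]))
    data.frame(z = zs,
               xmin = vapply(zs, function(z) min(p[p[, 3] == z, 1]), 1),
               xmax = vapply(zs, function(z) max(p[p[, 3] == z, 1]), 1))
  }
  structure(list(outer_anterior = rbind(ax_out, sg_out),
                 inner_anterior = rbind(ax_in, sg_in),
                 posterior = post,
                 slices_outer = slice_info(ax_out),
                 slices_inner = slice_info(ax_in),
                 slices_posterior = slice_info(post)),
            class = "contour_set")
}

# Deterministically thin a control point set to at most n_max points.
thin_points <- function(pts, n_max) {
  if (nrow(pts) <= n_max) return(pts)
  ord <- order(pts[, 3], pts[, 1], pts[, 2])
  pts[ord[round(seq(1, nrow(pts), length.out = n_max))], , drop = FALSE]
}

#' Interpolate abdominal wall surfaces from sparse contours
#'
#' Fits height-field thin-plate splines y = f(x, z) to the outer anterior,
#' inner anterior and posterior wall contour points and assembles the closed
#' cavity representation.
#'
#' @param contours a `contour_set` from `contours_from_labels()`, or a
#'   `labeled_volume` (contours are extracted first).
#' @param lambda TPS regularization (default 0: labels treated as exact).
#' @param max_control cap on TPS control points per surface (thinned
#'   deterministically above this).
#' @return object of class `wall_surfaces`.
#' @export
interpolate_walls <- function(contours, lambda = 0, max_control = 900L) {
  if (inherits(contours, "labeled_volume"))
    contours <- contours_from_labels(contours)
  stopifnot(inherits(contours, "contour_set"))
  for (nm in c("slices_outer", "slices_inner")) {
    si <- contours[[nm]]
    if (is.null(si) || nrow(si) < 2L)
      stop_hq(sprintf("need axial wall contours on >= 2 slices (%s)", nm))
  }
  fit_surface <- function(pts) {
    pts <- thin_points(pts, max_control)
    # jitter-free dedupe on (x, z): keep the mean y of coincident columns
    key <- paste(round(pts[, 1], 6), round(pts[, 3], 6))
    if (anyDuplicated(key)) {
      y_agg <- tapply(pts[, 2], key, mean)
      first <- !duplicated(key)
      pts <- pts[first, , drop = FALSE]
      pts[, 2] <- as.numeric(y_agg[paste(round(pts[, 1], 6), round(pts[, 3], 6))])
    }
    fit_tps(pts[, c(1, 3)], pts[, 2], lambda)
  }
  surf <- list(
    outer = fit_surface(contours$outer_anterior),
    inner = fit_surface(contours$inner_anterior),
    posterior = fit_surface(contours$posterior),
    slices_outer = contours$slices_outer,
    slices_inner = contours$slices_inner,
    slices_posterior = contours$slices_posterior,
    lambda = lambda,
    z_range = range(contours$slices_inner$z))
  structure(surf, class = "wall_surfaces")
}

# Linearly interpolated per-z lateral footprint [xmin, xmax] of a structure.
surface_footprint <- function(slices, z) {
  c(approx(slices$z, slices$xmin, z, rule = 2)$y,
    approx(slices$z, slices$xmax, z, rule = 2)$y)
}

#' Closed cavity cross-section polygon at an axial level
#'
#' Inner anterior curve (left to right) joined to the posterior curve
#' (right to left) by straight chords across the lateral gaps.
#'
#' @param surfaces a `wall_surfaces`.
#' @param z axial level in mm (inside the labeled range).
#' @param n curve samples per wall.
#' @return matrix with columns x, y (polygon vertices in order).
#' @export
cavity_cross_section <- function(surfaces, z, n = 80L) {
  fp_i <- surface_footprint(surfaces$slices_inner, z)
  fp_p <- surface_footprint(surfaces$slices_posterior, z)
  xi <- seq(fp_i[1], fp_i[2], length.out = n)
  xp <- seq(fp_p[1], fp_p[2], length.out = n)
  yi <- predict(surfaces$inner, cbind(xi, z))
  yp <- predict(surfaces$posterior, cbind(xp, z))
  cbind(x = c(xi, rev(xp)), y = c(yi, rev(yp)))
}

#' Cavity volume over a vertical range
#'
#' Integrates the closed cross-section area over z (trapezoidal rule on a
#' fine grid); flat caps at the range ends.
#'
#' @param surfaces a `wall_surfaces`.
#' @param z_range mm interval; defaults to the labeled range.
#' @param dz integration step in mm.
#' @param n curve samples per wall per level.
#' @return volume in cm^3.
#' @export
cavity_volume <- function(surfaces, z_range = surfaces$z_range, dz = 4, n = 80L) {
  zs <- seq(z_range[1], z_range[2], length.out = max(2L, ceiling(diff(z_range) / dz) + 1L))
  areas <- vapply(zs, function(z) {
    poly <- cavity_cross_section(surfaces, z, n)
    polygon_area(poly[, 1], poly[, 2])
  }, 1)
  h <- diff(zs)
  sum((areas[-1] + areas[-length(areas)]) / 2 * h) / 1e3
}

# Check that the cavity representation is closed (valid simple polygon with
# positive area at sampled levels; anterior curve above posterior curve).
cavity_is_closed <- function(surfaces, n_levels = 7L) {
  zs <- seq(surfaces$z_range[1], surfaces$z_range[2], length.out = n_levels)
  all(vapply(zs, function(z) {
    poly <- cavity_cross_section(surfaces, z)
    k <- nrow(poly) / 2
    polygon_area(poly[, 1], poly[, 2]) > 0 &&
      mean(poly[1:k, 2]) > mean(poly[(k + 1):(2 * k), 2])
  }, logical(1)))
}

#' Abdominal wall thickness statistics
#'
#' Samples the outer anterior surface over the common footprint and measures
#' the distance to the inner anterior surface along the outer surface
#' normal. Samples where the surfaces intersect (negative thickness) are
#' excluded with a warning.
#'
#' @param surfaces a `wall_surfaces`.
#' @param n_x,n_z sampling grid size.
#' @param trim fraction of the lateral footprint trimmed at each edge (the
#'   height field is steep there and normals leave the footprint).
#' @param max_depth maximum thickness searched, mm.
#' @return list with `mean_cm`, `sd_cm`, `n_samples`.
#' @export
wall_thickness_stats <- function(surfaces, n_x = 24L, n_z = 16L, trim = 0.12,
                                 max_depth = 80) {
  zr <- surfaces$z_range
  zs <- seq(zr[1] + 0.02 * diff(zr), zr[2] - 0.02 * diff(zr), length.out = n_z)
  samples <- numeric(0)
  n_neg <- 0L
  for (z in zs) {
    fo <- surface_footprint(surfaces$slices_outer, z)
    fi <- surface_footprint(surfaces$slices_inner, z)
    lo <- max(fo[1], fi[1]); hi <- min(fo[2], fi[2])
    wdt <- hi - lo
    xs <- seq(lo + trim * wdt, hi - trim * wdt, length.out = n_x)
    y0 <- predict(surfaces$outer, cbind(xs, z))
    h <- 0.5
    fx <- (predict(surfaces$outer, cbind(xs + h, z)) -
           predict(surfaces$outer, cbind(xs - h, z))) / (2 * h)
    fz <- (predict(surfaces$outer, cbind(xs, z + h)) -
           predict(surfaces$outer, cbind(xs, z - h))) / (2 * h)
    nn <- sqrt(fx^2 + 1 + fz^2)
    for (i in seq_along(xs)) {
      nv <- c(-fx[i], 1, -fz[i]) / nn[i]    # outward (anterior) normal
      g <- function(s) {
        (y0[i] - s * nv[2]) -
          predict(surfaces$inner, cbind(xs[i] - s * nv[1], z - s * nv[3]))
      }
      g0 <- g(0)
      if (g0 < 0) { n_neg <- n_neg + 1L; next }
      gmax <- tryCatch(g(max_depth), error = function(e) NA_real_)
      if (!is.finite(gmax) || gmax > 0) next
      s_root <- uniroot(g, c(0, max_depth), tol = 1e-6)$root
      samples <- c(samples, s_root)
    }
  }
  if (n_neg > 0L)
    warning(sprintf("wall_thickness_stats: %d negative-thickness samples excluded", n_neg))
  if (!length(samples)) stop_hq("no valid wall thickness samples")
  list(mean_cm = mean(samples) / 10, sd_cm = stats::sd(samples) / 10,
       n_samples = length(samples))
}
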