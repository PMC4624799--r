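# Synthetic labeled CT phantoms with analytic ground truth.
#
# The torso is an elliptic cylinder: a subcutaneous fat layer of constant
# depth under the skin, a muscular abdominal wall whose thickness varies
# sinusoidally along z, and an abdominal cavity containing a visceral fat
# ellipse and a bony "spine" disc. A ventral hernia is modeled as an outward
# half-ellipsoid cap whose cut plane crosses the anterior wall. All ground
# truth is computed from the continuous geometry, never from the voxel grid.

#' Specify a synthetic CT phantom
#'
#' Defaults emulate clinically observed conditions: ~1 mm in-plane and 5 mm
#' slice spacing, ~400 mm field of view, a 35 cm labeled abdominal range with
#' wall contours labeled every 5 cm, and tissue intensities at standard CT
#' Hounsfield levels.
#'
#' @param torso_semiaxes skin ellipse semi-axes (x, y) in mm.
#' @param height volume z extent in mm.
#' @param spacing voxel spacing in mm (x, y, z).
#' @param subcut_thickness subcutaneous fat layer depth in mm.
#' @param wall_thickness_mean,wall_thickness_amp,wall_period muscular wall
#'   thickness model t(z) = mean + amp * sin(2*pi*z/period), in mm.
#' @param visceral_semiaxes semi-axes of the visceral fat ellipse in mm.
#' @param spine_radius radius of the bone disc in mm.
#' @param hernia NULL for no hernia, or a list with `center_x`, `center_z`
#'   (mm), `semiaxes` (rx, ry, rz in mm; ry is the outward A-P semi-axis) and
#'   `depth` (mm the cut plane sits below the local skin apex; must satisfy
#'   0 < depth < ry so that the cap crosses the wall).
#' @param label_z_range z interval (mm) over which walls are labeled.
#' @param axial_spacing spacing between labeled axial slices in mm.
#' @param sagittal_offsets x offsets (mm from torso center) of labeled
#'   sagittal slices.
#' @param n_contour_points contour samples per structure per slice.
#' @param contour_gap_deg lateral angular gap (degrees) left unlabeled at the
#'   left/right extremes of anterior and posterior contours.
#' @param intensity_means,intensity_sd Hounsfield means for air, fat, muscle,
#'   bone, table, and the shared Gaussian noise SD.
#' @param margin in-plane air margin around the torso in mm.
#' @param seed integer seed fixing all randomness.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(torso_semiaxes = c(180, 140),
                         height = 400,
                         spacing = c(1, 1, 5),
                         subcut_thickness = 50,
                         wall_thickness_mean = 13.8,
                         wall_thickness_amp = 8,
                         wall_period = 200,
                         visceral_semiaxes = c(55, 34),
                         spine_radius = 15,
                         hernia = list(center_x = NULL, center_z = NULL,
                                       semiaxes = c(60, 30, 80), depth = 8),
                         label_z_range = c(25, 375),
                         axial_spacing = 50,
                         sagittal_offsets = c(-40, 0, 40),
                         n_contour_points = 64,
                         contour_gap_deg = 10,
                         intensity_means = c(air = -1000, fat = -90,
                                             muscle = 40, bone = 700,
                                             table = 300),
                         intensity_sd = 15,
                         margin = 40,
                         seed = 1L) {
  if (any(spacing <= 0)) stop_hq("spacing must be positive")
  if (axial_spacing < spacing[3])
    stop_hq("axial label-slice spacing must be >= slice thickness")
  if (label_z_range[1] >= label_z_range[2] || label_z_range[2] > height)
    stop_hq("invalid label_z_range")
  if (!is.null(hernia)) {
    if (is.null(hernia$center_x)) hernia$center_x <- 0
    if (is.null(hernia$center_z))
      hernia$center_z <- mean(label_z_range) + 20
    if (hernia$depth <= 0 || hernia$depth >= hernia$semiaxes[2])
      stop_hq(paste("hernia cap does not cross the anterior wall:",
                    "require 0 < depth < A-P semi-axis"),
              class = "herniaquant_spec_error")
  }
  structure(list(torso_semiaxes = torso_semiaxes, height = height,
                 spacing = spacing, subcut_thickness = subcut_thickness,
                 wall_thickness_mean = wall_thickness_mean,
                 wall_thickness_amp = wall_thickness_amp,
                 wall_period = wall_period,
                 visceral_semiaxes = visceral_semiaxes,
                 spine_radius = spine_radius, hernia = hernia,
                 label_z_range = label_z_range, axial_spacing = axial_spacing,
                 sagittal_offsets = sagittal_offsets,
                 n_contour_points = n_contour_points,
                 contour_gap_deg = contour_gap_deg,
                 intensity_means = intensity_means,
                 intensity_sd = intensity_sd, margin = margin,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Wall thickness profile t(z), mm.
phantom_wall_t <- function(spec, z) {
  spec$wall_thickness_mean +
    spec$wall_thickness_amp * sin(2 * pi * z / spec$wall_period)
}

# Geometry derived from a spec: torso center and skin apex helper.
phantom_frame <- function(spec) {
  a <- spec$torso_semiaxes[1]; b <- spec$torso_semiaxes[2]
  cx <- a + spec$margin
  extra_front <- if (!is.null(spec$hernia))
    max(0, spec$hernia$semiaxes[2] - spec$hernia$depth) else 0
  cy <- b + spec$margin + 35          # leave room for the scan table below
  lx <- 2 * a + 2 * spec$margin
  ly <- 2 * b + 2 * spec$margin + 35 + extra_front
  list(a = a, b = b, cx = cx, cy = cy, lx = lx, ly = ly, lz = spec$height)
}

# y of the anterior skin at a given x (upper half of the skin ellipse).
skin_front_y <- function(fr, x) {
  u <- 1 - ((x - fr$cx) / fr$a)^2
  if (u < 0) stop_hq("x outside torso for skin_front_y")
  fr$cy + fr$b * sqrt(u)
}

# Point on the inward-offset curve of the skin ellipse at parameter theta.
ellipse_offset_point <- function(fr, theta, d) {
  nx <- fr$b * cos(theta); ny <- fr$a * sin(theta)
  nn <- sqrt(nx^2 + ny^2)
  cbind(fr$cx + fr$a * cos(theta) - d * nx / nn,
        fr$cy + fr$b * sin(theta) - d * ny / nn)
}

# Anterior offset-curve y at a given x (solve for theta in (0, pi)).
offset_front_y <- function(fr, x, d) {
  f <- function(th) ellipse_offset_point(fr, th, d)[, 1] - x
  th <- uniroot(f, c(1e-6, pi - 1e-6), tol = 1e-10)$root
  ellipse_offset_point(fr, th, d)[, 2]
}

# Unsigned distance from in-plane points to the skin ellipse boundary.
dist_to_skin <- function(fr, px, py, n_boundary = 2048L) {
  th <- seq(0, 2 * pi, length.out = n_boundary + 1L)[-1L]
  bx <- fr$cx + fr$a * cos(th); by <- fr$cy + fr$b * sin(th)
  cross_min_dist(cbind(px, py, 0), cbind(bx, by, 0))
}

# Hernia half-ellipsoid membership for mm coordinates (vectorized).
hernia_inside <- function(spec, fr, x, y, z) {
  h <- spec$hernia
  if (is.null(h)) return(rep(FALSE, length(x)))
  hx <- fr$cx + h$center_x
  y_cut <- skin_front_y(fr, hx) - h$depth
  r <- h$semiaxes
  ((x - hx) / r[1])^2 + ((y - y_cut) / r[2])^2 + ((z - h$center_z) / r[3])^2 <= 1 &
    y >= y_cut
}

phantom_landmarks <- function(spec, fr) {
  zr <- spec$label_z_range
  list(
    xiphoid        = c(fr$cx, skin_front_y(fr, fr$cx) - 18, zr[2] - 5),
    umbilicus      = c(fr$cx, skin_front_y(fr, fr$cx), mean(zr)),
    asis_left      = c(fr$cx - 0.72 * fr$a, fr$cy + 0.45 * fr$b, zr[1] + 15),
    asis_right     = c(fr$cx + 0.72 * fr$a, fr$cy + 0.45 * fr$b, zr[1] + 15),
    pubic_symphysis = c(fr$cx, fr$cy + 0.55 * fr$b, max(5, zr[1] - 15)))
}

# Analytic ground truth; quadrature over the continuous geometry only.
phantom_ground_truth <- function(spec) {
  fr <- phantom_frame(spec)
  zr <- spec$label_z_range
  zrange <- diff(zr)
  s <- spec$subcut_thickness
  L <- ellipse_perimeter(fr$a, fr$b)
  area_at_depth <- function(d) pi * fr$a * fr$b - d * L + pi * d^2
  cavity <- integrate(function(z) area_at_depth(s + phantom_wall_t(spec, z)),
                      zr[1], zr[2], rel.tol = 1e-9)$value
  ring_area <- pi * fr$a * fr$b - area_at_depth(s)
  wall_mean <- integrate(function(z) phantom_wall_t(spec, z), zr[1], zr[2],
                         rel.tol = 1e-9)$value / zrange
  wall_msq <- integrate(function(z) phantom_wall_t(spec, z)^2, zr[1], zr[2],
                        rel.tol = 1e-9)$value / zrange
  wall_sd <- sqrt(max(0, wall_msq - wall_mean^2))

  hv <- 0; h_centroid <- NULL; h_out <- 0; h_ring <- 0; h_extents <- c(0, 0, 0)
  if (!is.null(spec$hernia)) {
    r <- spec$hernia$semiaxes
    hx <- fr$cx + spec$hernia$center_x
    y_cut <- skin_front_y(fr, hx) - spec$hernia$depth
    hv <- (2 / 3) * pi * prod(r)
    h_centroid <- c(hx, y_cut + 3 * r[2] / 8, spec$hernia$center_z)
    h_extents <- c(2 * r[1], r[2], 2 * r[3])
    # quadrature over the hernia bounding box at ~1 mm for skin overlaps
    gx <- seq(hx - r[1], hx + r[1], by = 1)
    gy <- seq(y_cut, y_cut + r[2], by = 1)
    gz <- seq(spec$hernia$center_z - r[3], spec$hernia$center_z + r[3], by = 2)
    gz <- gz[gz >= zr[1] & gz <= zr[2]]
    gg <- expand.grid(x = gx, y = gy)
    depth_g <- dist_to_skin(fr, gg$x, gg$y)
    inside_skin <- ((gg$x - fr$cx) / fr$a)^2 + ((gg$y - fr$cy) / fr$b)^2 <= 1
    cell <- 1 * 1 * 2
    for (z in gz) {
      inh <- hernia_inside(spec, fr, gg$x, gg$y, rep(z, nrow(gg)))
      h_out <- h_out + sum(inh & !inside_skin) * cell
      h_ring <- h_ring + sum(inh & inside_skin & depth_g < s) * cell
    }
  }
  body <- pi * fr$a * fr$b * zrange + h_out
  subcut <- ring_area * zrange - h_ring
  visceral <- pi * prod(spec$visceral_semiaxes) * zrange
  lms <- phantom_landmarks(spec, fr)
  list(hernia_volume_cm3 = hv / 1e3,
       hernia_extents_cm = h_extents / 10,
       hernia_centroid_mm = h_centroid,
       cavity_volume_cm3 = cavity / 1e3,
       body_volume_cm3 = body / 1e3,
       visceral_fat_cm3 = visceral / 1e3,
       subcutaneous_fat_cm3 = subcut / 1e3,
       wall_mean_cm = wall_mean / 10,
       wall_sd_cm = wall_sd / 10,
       evaluated_height_cm = zrange / 10,
       landmarks_mm = lms)
}

# Rasterize mm points into the label grid with a given code.
rasterize_points <- function(labels, spacing, pts, code, radius_vox = 0L) {
  dm <- dim(labels)
  # voxel centers sit at (i + 0.5) * spacing, i 0-based
  idx <- cbind(round(pts[, 1] / spacing[1] - 0.5),
               round(pts[, 2] / spacing[2] - 0.5),
               round(pts[, 3] / spacing[3] - 0.5))
  if (radius_vox > 0L) {
    off <- expand.grid(dx = -radius_vox:radius_vox, dy = -radius_vox:radius_vox,
                       dz = 0L)
    idx <- do.call(rbind, lapply(seq_len(nrow(off)), function(k)
      sweep(idx, 2L, as.numeric(off[k, ]), "+")))
  }
  ok <- idx[, 1] >= 0 & idx[, 1] < dm[1] & idx[, 2] >= 0 & idx[, 2] < dm[2] &
        idx[, 3] >= 0 & idx[, 3] < dm[3]
  idx <- idx[ok, , drop = FALSE]
  labels[idx[, 1] + dm[1] * (idx[, 2] + dm[2] * idx[, 3]) + 1L] <- code
  labels
}

#' Generate a labeled CT phantom with analytic ground truth
#'
#' Produces a [labeled_volume()] whose wall contours appear only on the
#' sparse labeled axial/sagittal slices, whose hernia label is dense on every
#' slice it crosses, and whose intensities are drawn from the configured
#' tissue distributions, together with ground-truth quantities computed from
#' the continuous geometry.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `volume` (a `labeled_volume`) and
#'   `ground_truth` (list of analytic values).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  fr <- phantom_frame(spec)
  sp <- spec$spacing
  dm <- c(ceiling(fr$lx / sp[1]), ceiling(fr$ly / sp[2]), ceiling(fr$lz / sp[3]))
  xs <- (seq_len(dm[1]) - 0.5) * sp[1]
  ys <- (seq_len(dm[2]) - 0.5) * sp[2]
  zs <- (seq_len(dm[3]) - 0.5) * sp[3]

  # in-plane, z-independent fields
  gx <- matrix(xs, dm[1], dm[2])
  gy <- matrix(ys, dm[1], dm[2], byrow = TRUE)
  inside_skin <- ((gx - fr$cx) / fr$a)^2 + ((gy - fr$cy) / fr$b)^2 <= 1
  depth <- matrix(Inf, dm[1], dm[2])
  w <- which(inside_skin)
  depth[w] <- dist_to_skin(fr, gx[w], gy[w])
  vis <- ((gx - fr$cx) / spec$visceral_semiaxes[1])^2 +
         ((gy - fr$cy) / spec$visceral_semiaxes[2])^2 <= 1
  spine_c <- c(fr$cx, fr$cy - 0.55 * fr$b)
  spine <- (gx - spine_c[1])^2 + (gy - spine_c[2])^2 <= spec$spine_radius^2
  table_slab <- abs(gx - fr$cx) <= 160 & gy >= 5 & gy <= 20

  s <- spec$subcut_thickness
  im <- spec$intensity_means
  hu <- matrix(0, dm[1], dm[2])
  class_stack <- array(0L, dim = dm)     # 1 fat, 2 muscle, 3 bone, 4 table
  for (k in seq_len(dm[3])) {
    z <- zs[k]
    t_z <- phantom_wall_t(spec, z)
    cls <- matrix(0L, dm[1], dm[2])
    cls[inside_skin & depth < s] <- 1L                         # subcutaneous fat
    cls[inside_skin & depth >= s & depth < s + t_z] <- 2L      # wall muscle
    cav <- inside_skin & depth >= s + t_z
    cls[cav] <- 2L                                             # organs ~ soft tissue
    cls[cav & vis] <- 1L                                       # visceral fat
    cls[cav & spine] <- 3L                                     # bone
    cls[!inside_skin & table_slab] <- 4L
    if (!is.null(spec$hernia)) {
      inh <- hernia_inside(spec, fr, as.vector(gx), as.vector(gy),
                           rep(z, length(gx)))
      cls[matrix(inh, dm[1], dm[2])] <- 2L                     # sac contents
    }
    class_stack[, , k] <- cls
  }

  intensity <- with_seed(spec$seed, {
    means <- c(im[["air"]], im[["fat"]], im[["muscle"]], im[["bone"]],
               im[["table"]])[class_stack + 1L]
    array(means + rnorm(length(class_stack), 0, spec$intensity_sd), dim = dm)
  })

  # ---- labels ----
  labels <- array(0L, dim = dm)
  reg <- label_registry()
  gap <- spec$contour_gap_deg * pi / 180
  np <- spec$n_contour_points
  th_ant <- seq(gap, pi - gap, length.out = np)
  th_post <- seq(pi + gap, 2 * pi - gap, length.out = np)
  zr <- spec$label_z_range
  axial_z <- seq(zr[1], zr[2], by = spec$axial_spacing)
  axial_z <- zs[vapply(axial_z, function(z) which.min(abs(zs - z)), 1L)]
  for (z in axial_z) {
    t_z <- phantom_wall_t(spec, z)
    po <- ellipse_offset_point(fr, th_ant, s)
    pi_ <- ellipse_offset_point(fr, th_ant, s + t_z)
    pp <- ellipse_offset_point(fr, th_post, s + t_z)
    labels <- rasterize_points(labels, sp, cbind(po, z), reg[["outer_wall_axial"]])
    labels <- rasterize_points(labels, sp, cbind(pi_, z), reg[["inner_wall_axial"]])
    labels <- rasterize_points(labels, sp, cbind(pp, z), reg[["posterior_wall"]])
    # fascial boundary points on the outer wall
    la <- ellipse_offset_point(fr, pi / 2, s)
    labels <- rasterize_points(labels, sp, cbind(la, z), reg[["linea_alba"]])
    for (sgn in c(-1, 1)) {
      th_sl <- acos(sgn * 60 / fr$a)
      sl <- ellipse_offset_point(fr, th_sl, s)
      labels <- rasterize_points(labels, sp, cbind(sl, z), reg[["linea_semilunaris"]])
    }
  }
  zs_lab <- zs[zs >= zr[1] & zs <= zr[2]]
  for (x_off in spec$sagittal_offsets) {
    x0 <- fr$cx + x_off
    yo <- offset_front_y(fr, x0, s)
    pts_o <- cbind(x0, yo, zs_lab)
    yi <- vapply(zs_lab, function(z) offset_front_y(fr, x0, s + phantom_wall_t(spec, z)), 1)
    pts_i <- cbind(x0, yi, zs_lab)
    labels <- rasterize_points(labels, sp, pts_o, reg[["outer_wall_sagittal"]])
    labels <- rasterize_points(labels, sp, pts_i, reg[["inner_wall_sagittal"]])
  }
  # dense hernia label (overwrites wall labels across the defect)
  if (!is.null(spec$hernia)) {
    hz <- spec$hernia$center_z; rz3 <- spec$hernia$semiaxes[3]
    for (k in which(abs(zs - hz) <= rz3)) {
      inh <- hernia_inside(spec, fr, as.vector(gx), as.vector(gy),
                           rep(zs[k], length(gx)))
      pl <- labels[, , k]
      pl[matrix(inh, dm[1], dm[2])] <- reg[["hernia"]]
      labels[, , k] <- pl
    }
  }
  lms <- phantom_landmarks(spec, fr)
  for (nm in names(lms)) {
    code <- reg[[switch(nm, xiphoid = "xiphoid", umbilicus = "umbilicus",
                        asis_left = "asis_left", asis_right = "asis_right",
                        pubic_symphysis = "pubic_symphysis")]]
    labels <- rasterize_points(labels, sp, matrix(lms[[nm]], ncol = 3),
                               code, radius_vox = 1L)
  }
  vol <- labeled_volume(intensity, labels, sp, origin = sp / 2)
  list(volume = vol, ground_truth = phantom_ground_truth(spec))
}

#' Perturb labels to emulate a second rater
#'
#' Wall contour voxels are displaced along the local contour normal by
#' zero-mean Gaussian noise; landmark structures are displaced rigidly by an
#' isotropic Gaussian offset; the hernia mask boundary is eroded/dilated at
#' random voxels with a probability scaled to the surface noise.
#'
#' @param vol a `labeled_volume`.
#' @param surface_noise_mm SD of contour-normal noise (mm), >= 0.
#' @param landmark_noise_mm SD per axis of landmark offsets (mm), >= 0.
#' @param seed integer seed.
#' @param hernia_flip_prob probability of flipping a hernia boundary voxel;
#'   default scales with `surface_noise_mm` relative to in-plane spacing.
#' @return perturbed `labeled_volume`.
#' @export
perturb_labels <- function(vol, surface_noise_mm, landmark_noise_mm, seed = 1L,
                           hernia_flip_prob = NULL) {
  if (surface_noise_mm < 0 || landmark_noise_mm < 0)
    stop_hq("noise magnitudes must be >= 0")
  if (surface_noise_mm == 0 && landmark_noise_mm == 0 &&
      (is.null(hernia_flip_prob) || hernia_flip_prob == 0)) return(vol)
  if (is.null(hernia_flip_prob))
    hernia_flip_prob <- min(0.9, 0.5 * surface_noise_mm / mean(vol$spacing[1:2]))
  reg <- label_registry()
  dm <- dim(vol$labels)
  labels <- vol$labels
  with_seed(seed, {
    # axial contours: displace radially from the per-slice contour centroid
    for (code in reg[c("outer_wall_axial", "inner_wall_axial", "posterior_wall")]) {
      w <- which(labels == code)
      if (!length(w)) next
      idx <- arrayInd(w, dm) - 1L
      pts <- voxel_to_mm(vol, idx)
      labels[w] <- 0L
      for (zv in unique(idx[, 3])) {
        sel <- idx[, 3] == zv
        p <- pts[sel, , drop = FALSE]
        ctr <- c(mean(p[, 1]), mean(p[, 2]))
        nrm <- cbind(p[, 1] - ctr[1], p[, 2] - ctr[2])
        nrm <- nrm / sqrt(rowSums(nrm^2))
        d <- rnorm(nrow(p), 0, surface_noise_mm)
        p[, 1:2] <- p[, 1:2] + nrm * d
        labels <- rasterize_points(labels, vol$spacing, p, code)
      }
    }
    # sagittal contours: displace along the in-column (y, z) curve normal
    for (code in reg[c("outer_wall_sagittal", "inner_wall_sagittal")]) {
      w <- which(labels == code)
      if (!length(w)) next
      idx <- arrayInd(w, dm) - 1L
      pts <- voxel_to_mm(vol, idx)
      labels[w] <- 0L
      for (xv in unique(idx[, 1])) {
        sel <- idx[, 1] == xv
        p <- pts[sel, , drop = FALSE]
        p <- p[order(p[, 3]), , drop = FALSE]
        n <- nrow(p)
        ty <- diff(p[c(1, seq_len(n)), 2]); tz <- diff(p[c(1, seq_len(n)), 3])
        ty[1] <- ty[2]; tz[1] <- tz[2]
        nn <- sqrt(ty^2 + tz^2); nn[nn == 0] <- 1
        d <- rnorm(n, 0, surface_noise_mm)
        p[, 2] <- p[, 2] + d * (tz / nn)
        p[, 3] <- p[, 3] - d * (ty / nn)
        labels <- rasterize_points(labels, vol$spacing, p, code)
      }
    }
    # landmarks and fascial boundaries: rigid isotropic offset per structure
    for (code in reg[c("linea_alba", "linea_semilunaris", "xiphoid", "umbilicus",
                       "asis_left", "asis_right", "pubic_symphysis")]) {
      w <- which(labels == code)
      if (!length(w)) next
      off <- rnorm(3, 0, landmark_noise_mm)
      idx <- arrayInd(w, dm) - 1L
      pts <- sweep(voxel_to_mm(vol, idx), 2L, off, "+")
      labels[w] <- 0L
      labels <- rasterize_points(labels, vol$spacing, pts, code)
    }
    # hernia: random boundary erosion/dilation
    hw <- which(labels == reg[["hernia"]])
    if (length(hw) && hernia_flip_prob > 0) {
      hmask <- array(FALSE, dm); hmask[hw] <- TRUE
      shift <- function(m, dx, dy, dz) {
        out <- array(FALSE, dm)
        xs <- seq_len(dm[1]); ys <- seq_len(dm[2]); zzs <- seq_len(dm[3])
        sx <- xs - dx; sy <- ys - dy; sz <- zzs - dz
        okx <- sx >= 1 & sx <= dm[1]; oky <- sy >= 1 & sy <= dm[2]
        okz <- sz >= 1 & sz <= dm[3]
        out[xs[okx], ys[oky], zzs[okz]] <- m[sx[okx], sy[oky], sz[okz]]
        out
      }
      nbr <- shift(hmask, 1, 0, 0) | shift(hmask, -1, 0, 0) |
             shift(hmask, 0, 1, 0) | shift(hmask, 0, -1, 0) |
             shift(hmask, 0, 0, 1) | shift(hmask, 0, 0, -1)
      inner_b <- which(hmask & !(shift(hmask, 1, 0, 0) & shift(hmask, -1, 0, 0) &
                                 shift(hmask, 0, 1, 0) & shift(hmask, 0, -1, 0)))
      outer_b <- which(nbr & !hmask & labels == 0L)
      drop_ <- inner_b[runif(length(inner_b)) < hernia_flip_prob]
      add_ <- outer_b[runif(length(outer_b)) < hernia_flip_prob]
      labels[drop_] <- 0L
      labels[add_] <- reg[["hernia"]]
    }
  })
  labeled_volume(vol$intensity, labels, vol$spacing, vol$origin)
}
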