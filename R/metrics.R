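# Derivation of the twenty hernia/body morphometrics (A-T).

#' Construct a metric vector
#'
#' @param ... named metric values among A-T; omitted entries are absent (NA).
#' @return object of class `metric_vector`.
#' @export
metric_vector <- function(...) {
  vals <- list(...)
  out <- setNames(as.list(rep(NA_real_, 20)), LETTERS[1:20])
  for (nm in names(vals)) {
    if (!nm %in% LETTERS[1:20]) stop_hq(sprintf("unknown metric '%s'", nm))
    out[[nm]] <- as.numeric(vals[[nm]])
  }
  structure(out, class = "metric_vector")
}

#' @export
print.metric_vector <- function(x, ...) {
  cat("metric_vector (A-T):\n")
  cat_ <- metric_catalog()
  for (i in 1:20) {
    v <- x[[cat_$index[i]]]
    cat(sprintf("  %s %-42s %s\n", cat_$index[i],
                paste0(cat_$name[i], ifelse(cat_$unit[i] == "", "",
                                            paste0(" (", cat_$unit[i], ")"))),
                ifelse(is.na(v), "absent", format(signif(v, 6)))))
  }
  invisible(x)
}

# Count exposed voxel faces of `mask` in a given axis direction.
boundary_faces <- function(mask, axis, dir) {
  dm <- dim(mask)
  shifted <- array(FALSE, dm)
  n <- dm[axis]
  idx_src <- if (dir > 0) 2:n else 1:(n - 1)
  idx_dst <- if (dir > 0) 1:(n - 1) else 2:n
  if (axis == 1) shifted[idx_dst, , ] <- mask[idx_src, , ]
  if (axis == 2) shifted[, idx_dst, ] <- mask[, idx_src, ]
  if (axis == 3) shifted[, , idx_dst] <- mask[, , idx_src]
  sum(mask & !shifted)
}

#' Hernia shape metrics (A-G)
#'
#' A: voxel volume; B/C/D: axis-aligned extents on x (L-R), y (A-P), z (C-C);
#' E/F: summed areas of exposed boundary voxel faces whose outward normal
#' points anteriorly (+y) / posteriorly (-y); G: mean A-P chord length over
#' occupied (x, z) columns. All in cm-based units.
#'
#' @param hernia logical hernia mask.
#' @param spacing voxel spacing in mm.
#' @return `metric_vector` with fields A-G set (all absent for empty mask).
#' @export
hernia_shape_metrics <- function(hernia, spacing) {
  if (!any(hernia)) return(metric_vector())
  dm <- dim(hernia)
  w <- which(hernia)
  idx <- arrayInd(w, dm)
  vox_cm3 <- prod(spacing) / 1e3
  ext <- vapply(1:3, function(ax)
    (max(idx[, ax]) - min(idx[, ax]) + 1L) * spacing[ax] / 10, 1)
  e_faces <- boundary_faces(hernia, 2L, +1L)
  f_faces <- boundary_faces(hernia, 2L, -1L)
  face_cm2 <- spacing[1] * spacing[3] / 100
  cols <- paste(idx[, 1], idx[, 3])
  chord <- tapply(rep(spacing[2], nrow(idx)), cols, sum)
  metric_vector(A = length(w) * vox_cm3,
                B = ext[1], C = ext[2], D = ext[3],
                E = e_faces * face_cm2, F = f_faces * face_cm2,
                G = mean(chord) / 10)
}

# Centroid (mm) of a mask on a labeled volume grid.
mask_centroid_mm <- function(mask, vol) {
  w <- which(mask)
  if (!length(w)) return(NULL)
  colMeans(voxel_to_mm(vol, arrayInd(w, dim(mask)) - 1L))
}

#' Hernia location metrics (H-L)
#'
#' H: projection fraction of the hernia centroid along the left-to-right
#' ASIS segment (0 at left ASIS, 1 at right ASIS; may leave \[0, 1\]);
#' I: vertical position of the centroid between the mean ASIS level (0) and
#' the xiphoid level (1; may be negative); J/K/L: Euclidean distances from
#' the centroid to left ASIS, right ASIS and xiphoid in cm.
#'
#' @param centroid hernia centroid in mm (length 3).
#' @param landmarks named list of mm points; requires `asis_left`,
#'   `asis_right`, `xiphoid`.
#' @return `metric_vector` with H-L set.
#' @export
hernia_location_metrics <- function(centroid, landmarks) {
  for (nm in c("asis_left", "asis_right", "xiphoid"))
    if (is.null(landmarks[[nm]]))
      stop_hq(sprintf("missing required landmark '%s'", nm))
  la <- landmarks$asis_left; ra <- landmarks$asis_right; xp <- landmarks$xiphoid
  seg <- ra - la
  if (sum(seg^2) == 0) stop_hq("left and right ASIS coincide")
  H <- sum((centroid - la) * seg) / sum(seg^2)
  asis_z <- mean(c(la[3], ra[3]))
  I <- (centroid[3] - asis_z) / (xp[3] - asis_z)
  d <- function(p) sqrt(sum((centroid - p)^2)) / 10
  metric_vector(H = H, I = I, J = d(la), K = d(ra), L = d(xp))
}

#' Body metrics (M-T)
#'
#' @param body logical body mask.
#' @param surfaces a `wall_surfaces`.
#' @param fat_split result of [split_fat()].
#' @param hernia_volume_cm3 hernia volume (0 when no hernia).
#' @param vol the `labeled_volume` (grid geometry).
#' @param thickness optional precomputed [wall_thickness_stats()] result.
#' @return `metric_vector` with M-T set.
#' @export
body_metrics <- function(body, surfaces, fat_split, hernia_volume_cm3, vol,
                         thickness = NULL) {
  zr <- surfaces$z_range
  zs <- vol$origin[3] + (seq_len(dim(body)[3]) - 1L) * vol$spacing[3]
  in_range <- zs >= zr[1] & zs <= zr[2]
  vox_cm3 <- prod(vol$spacing) / 1e3
  M <- sum(body[, , in_range]) * vox_cm3
  N <- cavity_volume(surfaces)
  if (is.null(thickness)) thickness <- wall_thickness_stats(surfaces)
  metric_vector(M = M, N = N,
                O = if (hernia_volume_cm3 > 0) hernia_volume_cm3 / N else 0,
                P = thickness$mean_cm, Q = thickness$sd_cm,
                R = fat_split$visceral_cm3, S = fat_split$subcutaneous_cm3,
                T = diff(zr) / 10)
}

#' Derive all twenty metrics from a labeled volume
#'
#' Orchestrates surface interpolation, body/fat segmentation and the metric
#' computations. Shape and location metrics are absent (NA, not zero) when
#' no hernia is labeled; O is 0 in that case.
#'
#' @param vol a `labeled_volume` with wall contours and landmarks (hernia
#'   optional).
#' @param lambda TPS regularization passed to [interpolate_walls()].
#' @return `metric_vector` with all available fields.
#' @export
derive_all <- function(vol, lambda = 0) {
  reg <- label_registry()
  surfaces <- tryCatch(interpolate_walls(vol, lambda = lambda),
                       error = function(e)
                         stop_hq(paste("surfaces stage:", conditionMessage(e))))
  body <- tryCatch(extract_body(vol),
                   error = function(e)
                     stop_hq(paste("body segmentation stage:", conditionMessage(e))))
  seg <- segment_fat(vol, body)
  fs <- split_fat(seg$fat, surfaces, vol)
  hernia <- vol$labels == reg[["hernia"]]
  out <- metric_vector()
  hv <- 0
  if (any(hernia)) {
    shape <- hernia_shape_metrics(hernia, vol$spacing)
    hv <- shape$A
    lms <- list(
      asis_left = landmark_representative_point(vol, "asis_left"),
      asis_right = landmark_representative_point(vol, "asis_right"),
      xiphoid = landmark_representative_point(vol, "xiphoid"))
    loc <- hernia_location_metrics(mask_centroid_mm(hernia, vol), lms)
    for (nm in LETTERS[1:7]) out[[nm]] <- shape[[nm]]
    for (nm in LETTERS[8:12]) out[[nm]] <- loc[[nm]]
  }
  bm <- body_metrics(body, surfaces, fs, hv, vol)
  for (nm in LETTERS[13:20]) out[[nm]] <- bm[[nm]]
  class(out) <- "metric_vector"
  out
}
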