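# Intra-/inter-rater reproducibility statistics between two label sets of
# the same scan: mean surface distance, Hausdorff distance, landmark
# Euclidean distances, and Cohen's kappa on the hernia mask.

#' Symmetric mean surface distance between two point sets
#'
#' Half the sum of the two directed mean nearest-neighbor distances.
#'
#' @param surfA,surfB n x 3 / m x 3 matrices of mm points.
#' @return MSD in mm.
#' @export
mean_surface_distance <- function(surfA, surfB) {
  surfA <- as.matrix(surfA); surfB <- as.matrix(surfB)
  if (!nrow(surfA) || !nrow(surfB)) stop_hq("empty point set")
  (mean(cross_min_dist(surfA, surfB)) + mean(cross_min_dist(surfB, surfA))) / 2
}

#' Symmetric Hausdorff distance between two point sets
#'
#' Maximum of the two directed maxima of nearest-neighbor distances.
#'
#' @inheritParams mean_surface_distance
#' @return HD in mm.
#' @export
hausdorff_distance <- function(surfA, surfB) {
  surfA <- as.matrix(surfA); surfB <- as.matrix(surfB)
  if (!nrow(surfA) || !nrow(surfB)) stop_hq("empty point set")
  max(max(cross_min_dist(surfA, surfB)), max(cross_min_dist(surfB, surfA)))
}

#' Representative point of a labeled landmark
#'
#' Dispatches the per-landmark rule: centroid for the xiphoid process, linea
#' alba and linea semilunaris; centermost labeled point (nearest the label
#' centroid) for the umbilicus; most superior point for the pubic symphysis;
#' most anterior point for each ASIS. Ties are broken deterministically by
#' most-superior, then most-right.
#'
#' @param vol a `labeled_volume`.
#' @param landmark one of `"xiphoid"`, `"umbilicus"`, `"asis_left"`,
#'   `"asis_right"`, `"pubic_symphysis"`, `"linea_alba"`,
#'   `"linea_semilunaris"`.
#' @return mm coordinate (length 3).
#' @export
landmark_representative_point <- function(vol, landmark) {
  reg <- label_registry()
  if (!landmark %in% names(reg)) stop_hq(sprintf("unknown landmark '%s'", landmark))
  pts <- label_points_mm(vol, reg[[landmark]])
  if (!nrow(pts)) stop_hq(sprintf("landmark '%s' not labeled", landmark))
  pick <- function(score) {
    ord <- order(-score, -pts[, 3], -pts[, 1])
    pts[ord[1], ]
  }
  switch(landmark,
    xiphoid = , linea_alba = , linea_semilunaris = colMeans(pts),
    umbilicus = {
      ctr <- colMeans(pts)
      pick(-rowSums(sweep(pts, 2L, ctr)^2))
    },
    pubic_symphysis = pick(pts[, 3]),
    asis_left = , asis_right = pick(pts[, 2]),
    stop_hq(sprintf("no representative-point rule for '%s'", landmark)))
}

#' Cohen's kappa between two binary masks
#'
#' Voxelwise chance-corrected agreement over a reference region.
#'
#' @param maskA,maskB logical arrays of identical shape.
#' @param region logical array; must contain the union of both masks.
#' @return kappa in \[-1, 1\], or NA (with a warning) when the marginals are
#'   degenerate (chance agreement is 1).
#' @export
cohen_kappa_masks <- function(maskA, maskB, region) {
  stopifnot(identical(dim(maskA), dim(maskB)), identical(dim(maskA), dim(region)))
  if (!any(region)) stop_hq("empty kappa region")
  if (any((maskA | maskB) & !region))
    stop_hq("region must contain the union of both masks")
  a <- maskA[region]; b <- maskB[region]
  n <- length(a)
  p_o <- mean(a == b)
  pa <- mean(a); pb <- mean(b)
  p_e <- pa * pb + (1 - pa) * (1 - pb)
  if (1 - p_e == 0) {
    warning("degenerate marginals: kappa undefined")
    return(NA_real_)
  }
  (p_o - p_e) / (1 - p_e)
}

# Bounding box of a union mask dilated by `margin` voxels, as a region mask.
kappa_region <- function(maskA, maskB, margin = 10L) {
  u <- maskA | maskB
  dm <- dim(u)
  if (!any(u)) return(array(TRUE, dm))
  idx <- arrayInd(which(u), dm)
  lo <- pmax(apply(idx, 2, min) - margin, 1L)
  hi <- pmin(apply(idx, 2, max) + margin, dm)
  region <- array(FALSE, dm)
  region[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  region
}

#' Reliability report between two labelings of the same scan
#'
#' Computes MSD and HD for the five wall structures, landmark Euclidean
#' distances for the seven landmark structures, and Cohen's kappa for the
#' hernia label (negative class restricted to the union bounding box dilated
#' by `kappa_margin` voxels; kappa depends on this choice, which is logged
#' in the report).
#'
#' @param volA,volB two `labeled_volume`s on the same grid.
#' @param kappa_margin dilation (voxels) of the kappa region.
#' @return object of class `reliability_report`: lists `wall` (per-structure
#'   msd/hd in mm), `landmarks` (ED in mm), `hernia_kappa`, and settings.
#'   Structures missing from either volume are reported as NA.
#' @export
reliability_report <- function(volA, volB, kappa_margin = 10L) {
  if (!identical(dim(volA$labels), dim(volB$labels)) ||
      !isTRUE(all.equal(volA$spacing, volB$spacing)))
    stop_hq("volumes must share grid geometry")
  reg <- label_registry()
  walls <- c("outer_wall_axial", "inner_wall_axial", "outer_wall_sagittal",
             "inner_wall_sagittal", "posterior_wall")
  wall_stats <- lapply(walls, function(st) {
    pA <- label_points_mm(volA, reg[[st]])
    pB <- label_points_mm(volB, reg[[st]])
    if (!nrow(pA) || !nrow(pB)) return(list(msd = NA_real_, hd = NA_real_))
    list(msd = mean_surface_distance(pA, pB), hd = hausdorff_distance(pA, pB))
  })
  names(wall_stats) <- walls
  lms <- c("xiphoid", "asis_left", "asis_right", "umbilicus", "linea_alba",
           "linea_semilunaris", "pubic_symphysis")
  lm_ed <- vapply(lms, function(lm) {
    pA <- tryCatch(landmark_representative_point(volA, lm), error = function(e) NULL)
    pB <- tryCatch(landmark_representative_point(volB, lm), error = function(e) NULL)
    if (is.null(pA) || is.null(pB)) return(NA_real_)
    sqrt(sum((pA - pB)^2))
  }, 1)
  hA <- volA$labels == reg[["hernia"]]
  hB <- volB$labels == reg[["hernia"]]
  kappa <- if (any(hA) || any(hB))
    cohen_kappa_masks(hA, hB, kappa_region(hA, hB, kappa_margin))
  else NA_real_
  structure(list(wall = wall_stats, landmarks = lm_ed, hernia_kappa = kappa,
                 settings = list(kappa_margin = kappa_margin)),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat("reliability report\n  wall structures (MSD / HD, mm):\n")
  for (nm in names(x$wall))
    cat(sprintf("    %-20s %6.2f / %6.2f\n", nm, x$wall[[nm]]$msd, x$wall[[nm]]$hd))
  cat("  landmarks (ED, mm):\n")
  for (nm in names(x$landmarks))
    cat(sprintf("    %-20s %6.2f\n", nm, x$landmarks[[nm]]))
  cat(sprintf("  hernia Cohen's kappa: %.3f\n", x$hernia_kappa))
  invisible(x)
}

#' Aggregate reliability reports over scan pairs
#'
#' @param reports list of `reliability_report`s.
#' @return list of data.frames with mean and SD per statistic, formatted as
#'   mean +/- SD per structure/landmark.
#' @export
aggregate_reliability <- function(reports) {
  stopifnot(length(reports) >= 1L)
  wall_names <- names(reports[[1]]$wall)
  agg <- function(get) {
    vals <- vapply(reports, get, 1)
    c(mean = mean(vals, na.rm = TRUE), sd = stats::sd(vals, na.rm = TRUE))
  }
  wall <- do.call(rbind, lapply(wall_names, function(nm)
    data.frame(structure = nm,
               msd_mean = agg(function(r) r$wall[[nm]]$msd)[1],
               msd_sd = agg(function(r) r$wall[[nm]]$msd)[2],
               hd_mean = agg(function(r) r$wall[[nm]]$hd)[1],
               hd_sd = agg(function(r) r$wall[[nm]]$hd)[2])))
  lm_names <- names(reports[[1]]$landmarks)
  lm <- do.call(rbind, lapply(lm_names, function(nm)
    data.frame(landmark = nm,
               ed_mean = agg(function(r) r$landmarks[[nm]])[1],
               ed_sd = agg(function(r) r$landmarks[[nm]])[2])))
  kap <- agg(function(r) r$hernia_kappa)
  list(wall = wall, landmarks = lm,
       hernia_kappa = data.frame(mean = kap[1], sd = kap[2]))
}
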