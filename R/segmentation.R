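# Intensity-based body extraction and fat/muscle separation by fuzzy C-means
# clustering, and the visceral/subcutaneous split by the cavity surface.

#' Fuzzy C-means clustering of scalar intensities
#'
#' Deterministic 1-D FCM: centers are initialized at intensity quantiles, so
#' repeated runs give identical results. Internally the data are binned to
#' 1 HU for speed; memberships are computed per bin.
#'
#' @param x numeric vector of intensities.
#' @param k number of clusters.
#' @param m fuzziness exponent (> 1).
#' @param tol convergence tolerance on center movement.
#' @param max_iter iteration cap.
#' @return list with `centers` (sorted ascending), `membership` (length(x)
#'   x k matrix, columns ordered by center), and `objective` (per-iteration
#'   trace of the FCM objective; non-increasing).
#' @export
fcm_cluster <- function(x, k = 2L, m = 2, tol = 1e-5, max_iter = 300L) {
  stopifnot(k >= 2L, m > 1)
  bins <- round(x)
  tab <- table(bins)
  v <- as.numeric(names(tab))
  wt <- as.numeric(tab)
  centers <- as.numeric(quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE))
  expo <- 2 / (m - 1)
  obj <- numeric(0)
  memb_bin <- NULL
  for (it in seq_len(max_iter)) {
    d2 <- outer(v, centers, function(a, b) (a - b)^2)
    d2 <- pmax(d2, 1e-12)
    inv <- d2^(-1 / (m - 1))
    memb_bin <- inv / rowSums(inv)
    um <- memb_bin^m * wt
    obj <- c(obj, sum(um * d2))
    new_centers <- colSums(um * v) / colSums(um)
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    if (shift < tol) break
  }
  ord <- order(centers)
  centers <- centers[ord]
  memb_bin <- memb_bin[, ord, drop = FALSE]
  idx <- match(bins, v)
  list(centers = centers, membership = memb_bin[idx, , drop = FALSE],
       objective = obj)
}

#' Extract the body mask from CT intensities
#'
#' Two-cluster FCM on intensity separates body from air; the higher-mean
#' cluster is thresholded at membership 0.5, the largest 26-connected
#' component is kept (which discards the scan table), and in-plane holes are
#' filled per axial slice.
#'
#' @param vol a `labeled_volume`.
#' @return logical 3-D body mask.
#' @export
extract_body <- function(vol) {
  fc <- fcm_cluster(as.vector(vol$intensity), k = 2L)
  # an all-air scan splits its noise into two clusters that both sit at air
  # level; there is no body to extract
  if (fc$centers[2] < -500)
    stop_hq("empty foreground: no body found (all intensities at air level)",
            class = "herniaquant_validation_error")
  if (diff(fc$centers) < 50)
    warning("extract_body: intensity clusters poorly separated")
  fg <- array(fc$membership[, 2] > 0.5, dim = dim(vol$intensity))
  if (!any(fg)) stop_hq("empty foreground: no body found",
                        class = "herniaquant_validation_error")
  body <- largest_component(fg, connectivity = 26L)
  fill_holes_axial(body)
}

#' Separate fat from muscle within the body
#'
#' Bone (> `bone_hu`) and air (< `air_hu`) are removed, then two-cluster FCM
#' on the remaining body intensities assigns the lower-mean cluster to fat
#' and the higher-mean cluster to muscle/soft tissue.
#'
#' @param vol a `labeled_volume`.
#' @param body logical body mask from [extract_body()].
#' @param bone_hu,air_hu exclusion thresholds in HU.
#' @return list of logical masks `fat`, `muscle`, `bone`, `air` and the two
#'   cluster `centers`.
#' @export
segment_fat <- function(vol, body, bone_hu = 200, air_hu = -500) {
  if (!any(body)) stop_hq("body mask is empty")
  bone <- body & vol$intensity > bone_hu
  air <- body & vol$intensity < air_hu
  soft <- body & !bone & !air
  xv <- vol$intensity[soft]
  fc <- fcm_cluster(xv, k = 2L)
  if (diff(fc$centers) < 40) {
    warning("segment_fat: fat and muscle intensity modes are not well separated; falling back to a fixed fat window (< -30 HU)")
    is_fat <- xv < -30
  } else {
    is_fat <- fc$membership[, 1] > 0.5
  }
  fat <- array(FALSE, dim(body)); muscle <- array(FALSE, dim(body))
  wsoft <- which(soft)
  fat[wsoft[is_fat]] <- TRUE
  muscle[wsoft[!is_fat]] <- TRUE
  list(fat = fat, muscle = muscle, bone = bone, air = air,
       centers = fc$centers)
}

#' Split fat into visceral and subcutaneous compartments
#'
#' Fat voxels whose centers fall inside the closed cavity cross-section are
#' visceral; fat voxels outside the cavity (but inside the body) are
#' subcutaneous. Volumes are voxel count x voxel volume, restricted to the
#' vertical range.
#'
#' @param fat logical fat mask.
#' @param surfaces a `wall_surfaces`.
#' @param vol the `labeled_volume` supplying grid geometry.
#' @param vertical_range mm interval (default: labeled wall range).
#' @param body optional body mask; if provided, fat voxels outside the body
#'   raise a validation error.
#' @return list with `visceral_cm3`, `subcutaneous_cm3`, and the two masks.
#' @export
split_fat <- function(fat, surfaces, vol, vertical_range = surfaces$z_range,
                      body = NULL) {
  if (!is.null(body) && any(fat & !body))
    stop_hq("fat voxels outside the body mask",
            class = "herniaquant_validation_error")
  if (!cavity_is_closed(surfaces))
    stop_hq("cavity surface is not closed over the requested range")
  dm <- dim(fat)
  zs <- vol$origin[3] + (seq_len(dm[3]) - 1L) * vol$spacing[3]
  in_range <- zs >= vertical_range[1] & zs <= vertical_range[2]
  visceral <- array(FALSE, dm); subcut <- array(FALSE, dm)
  vox_cm3 <- prod(vol$spacing) / 1e3
  for (k in which(in_range)) {
    w <- which(fat[, , k])
    if (!length(w)) next
    ij <- arrayInd(w, dm[1:2])
    pts <- cbind(vol$origin[1] + (ij[, 1] - 1L) * vol$spacing[1],
                 vol$origin[2] + (ij[, 2] - 1L) * vol$spacing[2])
    zq <- min(max(zs[k], surfaces$z_range[1]), surfaces$z_range[2])
    poly <- cavity_cross_section(surfaces, zq)
    inside <- mgcv::in.out(rbind(poly, poly[1, ]), pts)
    if (any(inside))
      visceral[cbind(ij[inside, , drop = FALSE], rep(k, sum(inside)))] <- TRUE
    if (any(!inside))
      subcut[cbind(ij[!inside, , drop = FALSE], rep(k, sum(!inside)))] <- TRUE
  }
  list(visceral_cm3 = sum(visceral) * vox_cm3,
       subcutaneous_cm3 = sum(subcut) * vox_cm3,
       visceral = visceral, subcutaneous = subcut)
}
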