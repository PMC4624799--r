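# Core containers and external formats: labeled CT volumes, the label-code
# registry, landmark sets, per-subject metric tables and cohort tables.

#' Label code registry
#'
#' Integer codes used in label volumes for every structure the pipeline
#' consumes. The encoding is a convention of this package.
#'
#' @return named integer vector of label codes.
#' @export
label_registry <- function() {
  c(outer_wall_axial    = 1L,
    inner_wall_axial    = 2L,
    posterior_wall      = 3L,
    outer_wall_sagittal = 4L,
    inner_wall_sagittal = 5L,
    linea_alba          = 6L,
    linea_semilunaris   = 7L,
    hernia              = 8L,
    xiphoid             = 10L,
    umbilicus           = 11L,
    asis_left           = 12L,
    asis_right          = 13L,
    pubic_symphysis     = 14L)
}

#' Construct a labeled CT volume
#'
#' Bundles an intensity grid (Hounsfield-like units) with a same-shape integer
#' label grid and the voxel geometry. Voxel indices are 0-based in mm
#' conversions; a voxel's mm coordinate is its center. Axes are fixed as
#' x = left-to-right, y = posterior-to-anterior, z = inferior-to-superior.
#'
#' @param intensity 3-D numeric array.
#' @param labels 3-D integer array, same shape as `intensity`.
#' @param spacing voxel size in mm, length 3, strictly positive.
#' @param origin mm coordinate of the center of voxel `[1, 1, 1]`.
#' @return object of class `labeled_volume`.
#' @export
labeled_volume <- function(intensity, labels, spacing, origin = c(0, 0, 0)) {
  if (!identical(dim(intensity), dim(labels)))
    stop_hq(sprintf("intensity/label shape mismatch: %s vs %s",
                    paste(dim(intensity), collapse = "x"),
                    paste(dim(labels), collapse = "x")),
            class = "herniaquant_format_error")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop_hq("spacing must be three strictly positive mm values")
  labs <- as.integer(labels)
  bad <- setdiff(unique(labs), c(0L, unname(label_registry())))
  if (length(bad))
    stop_hq(sprintf("unknown label code(s): %s", paste(sort(bad), collapse = ", ")),
            class = "herniaquant_validation_error")
  structure(list(intensity = intensity,
                 labels = array(labs, dim = dim(labels)),
                 spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  cat(sprintf("labeled_volume: %s voxels @ %s mm, origin (%s) mm\n",
              paste(dim(x$intensity), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  codes <- sort(unique(as.vector(x$labels)))
  cat("  label codes present:", paste(setdiff(codes, 0L), collapse = ", "), "\n")
  invisible(x)
}

#' Volume extent in mm along each axis
#' @param vol a `labeled_volume`.
#' @return length-3 numeric vector (mm).
#' @export
volume_extent <- function(vol) dim(vol$intensity) * vol$spacing

#' Map 0-based voxel indices to patient mm coordinates (voxel centers)
#' @param vol a `labeled_volume`.
#' @param idx n x 3 matrix of 0-based voxel indices.
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_to_mm <- function(vol, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3L)
  sweep(sweep(idx, 2L, vol$spacing, "*"), 2L, vol$origin, "+")
}

#' Map patient mm coordinates to (fractional) 0-based voxel indices
#' @param vol a `labeled_volume`.
#' @param mm n x 3 matrix of mm coordinates.
#' @return n x 3 matrix of fractional 0-based indices.
#' @export
mm_to_voxel <- function(vol, mm) {
  mm <- matrix(as.numeric(mm), ncol = 3L)
  sweep(sweep(mm, 2L, vol$origin, "-"), 2L, vol$spacing, "/")
}

# mm coordinates of all voxels carrying a given label code, n x 3.
label_points_mm <- function(vol, code) {
  w <- which(vol$labels == code)
  if (!length(w)) return(matrix(numeric(0), ncol = 3L))
  voxel_to_mm(vol, arrayInd(w, dim(vol$labels)) - 1L)
}

#' Read a paired intensity + label volume from NIfTI files
#'
#' @param image_path path to the intensity NIfTI.
#' @param label_path path to the label NIfTI (same grid).
#' @return a [labeled_volume()]; geometry is taken from the image header.
#' @export
read_labeled_volume <- function(image_path, label_path) {
  img <- read_nifti(image_path)
  lab <- read_nifti(label_path)
  if (!identical(dim(img$data), dim(lab$data)))
    stop_hq(sprintf("image/label grid mismatch: %s vs %s",
                    paste(dim(img$data), collapse = "x"),
                    paste(dim(lab$data), collapse = "x")),
            class = "herniaquant_format_error")
  labeled_volume(img$data, round(lab$data), img$spacing, img$origin)
}

#' Write a labeled volume as paired NIfTI files
#'
#' @param vol a `labeled_volume`.
#' @param image_path,label_path output paths.
#' @return invisibly, the two paths.
#' @export
write_labeled_volume <- function(vol, image_path, label_path) {
  write_nifti(vol$intensity, image_path, vol$spacing, vol$origin, "float32")
  write_nifti(vol$labels, label_path, vol$spacing, vol$origin, "int16")
  invisible(c(image_path, label_path))
}

#' The twenty derived metrics: indices, names and units
#'
#' Metrics A-G describe hernia shape, H-L hernia location relative to
#' landmarks, and M-T the surrounding body. The average A-P thickness (G) is
#' reported in cm.
#'
#' @return data.frame with columns `index`, `name`, `unit`, `column`.
#' @export
metric_catalog <- function() {
  data.frame(
    index = LETTERS[1:20],
    name = c("Hernia volume", "Hernia L-R diameter", "Hernia A-P diameter",
             "Hernia C-C diameter", "Hernia anterior surface area",
             "Hernia posterior surface area", "Average A-P hernia thickness",
             "Normalized horizontal hernia location",
             "Normalized vertical hernia location",
             "Distance from hernia to left ASIS",
             "Distance from hernia to right ASIS",
             "Distance from hernia to xiphoid process",
             "Body volume over abdomen", "Abdominal cavity volume",
             "Ratio of hernia to abdominal cavity volume",
             "Mean abdominal wall thickness", "Std of abdominal wall thickness",
             "Visceral fat volume", "Subcutaneous fat volume",
             "Evaluated height of abdominal region"),
    unit = c("cm3", "cm", "cm", "cm", "cm2", "cm2", "cm", "", "", "cm", "cm",
             "cm", "cm3", "cm3", "", "cm", "cm", "cm3", "cm3", "cm"),
    stringsAsFactors = FALSE)
}

metric_columns <- function() {
  cat <- metric_catalog()
  unit <- ifelse(cat$unit == "", "", paste0(" (", cat$unit, ")"))
  paste0(cat$index, ": ", cat$name, unit)
}

#' Write per-subject metric vectors to CSV
#'
#' One row per subject, 21 columns: subject id followed by metrics A-T with
#' their full names in the header. Absent metrics (hernia-free subjects) are
#' written as empty cells.
#'
#' @param rows named list of metric vectors (as returned by [derive_all()] or
#'   [metric_vector()]); names are subject ids. A single metric vector is
#'   also accepted.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(rows, path) {
  if (inherits(rows, "metric_vector")) rows <- list(subject = rows)
  if (!length(rows)) stop_hq("no metric rows to write")
  ids <- names(rows)
  if (is.null(ids)) ids <- sprintf("subject_%03d", seq_along(rows))
  mat <- t(vapply(rows, function(r) {
    v <- unclass(r)[LETTERS[1:20]]
    if (any(vapply(v, is.null, logical(1))))
      stop_hq("metric vector missing fields; all rows must expose A-T")
    as.numeric(unlist(v))
  }, numeric(20)))
  df <- data.frame(id = ids, mat, stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- c("id", metric_columns())
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a metric table written by [write_metrics_table()]
#' @param path CSV path.
#' @return data.frame with id column and metric columns A-T (named by index).
#' @export
read_metrics_table <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(ncol(df) == 21L)
  names(df) <- c("id", LETTERS[1:20])
  df
}

#' Construct a cohort table
#'
#' Subjects x features with a binary bridge-closure outcome
#' (1 = mesh bridge required, 0 = primary fascial closure).
#'
#' @param features numeric matrix or data.frame (subjects x features).
#' @param outcome binary vector (0/1), one per subject, no missing values.
#' @param id optional subject ids.
#' @return data.frame of class `cohort_table` with attribute `feature_names`.
#' @export
cohort_table <- function(features, outcome, id = NULL) {
  features <- as.data.frame(features)
  if (ncol(features) < 1L) stop_hq("cohort needs at least one feature column")
  if (anyNA(outcome)) stop_hq("cohort outcome contains missing values")
  outcome <- as.integer(outcome)
  if (!all(outcome %in% c(0L, 1L))) stop_hq("outcome must be binary 0/1")
  if (nrow(features) != length(outcome))
    stop_hq("feature rows and outcome length differ")
  if (is.null(id)) id <- sprintf("S%03d", seq_along(outcome))
  df <- cbind(data.frame(id = id, stringsAsFactors = FALSE), features,
              data.frame(bridge = outcome))
  structure(df, class = c("cohort_table", "data.frame"),
            feature_names = names(features))
}

#' Extract the feature matrix / outcome vector from a cohort table
#' @param cohort a `cohort_table`.
#' @return `cohort_features`: numeric matrix (subjects x features);
#'   `cohort_outcome`: integer 0/1 vector.
#' @export
cohort_features <- function(cohort) {
  as.matrix(cohort[, attr(cohort, "feature_names"), drop = FALSE])
}

#' @rdname cohort_features
#' @export
cohort_outcome <- function(cohort) cohort$bridge

#' Read / write cohort tables as CSV
#' @param path CSV path.
#' @param cohort a `cohort_table`.
#' @return `read_cohort_table`: a `cohort_table`; `write_cohort_table`: the
#'   path, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("id", "bridge") %in% names(df)))
    stop_hq("cohort CSV must have 'id' and 'bridge' columns")
  feats <- setdiff(names(df), c("id", "bridge"))
  cohort_table(df[, feats, drop = FALSE], df$bridge, df$id)
}
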