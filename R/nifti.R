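# Minimal single-file NIfTI-1 (.nii / .nii.gz) reader and writer.
#
# Only the subset of the format this package emits is supported: 3-D volumes,
# datatypes float32 (16), int16 (4) and int32 (8), scl_slope 1 / scl_inter 0,
# and an axis-aligned sform affine (no rotation). Both byte orders are read;
# files are written little-endian.

NIFTI_HDR_SIZE <- 348L
NIFTI_VOX_OFFSET <- 352

nifti_dtype <- function(storage) {
  switch(storage,
    float32 = list(code = 16L, bitpix = 32L, what = "numeric", size = 4L),
    int32   = list(code = 8L,  bitpix = 32L, what = "integer", size = 4L),
    int16   = list(code = 4L,  bitpix = 16L, what = "integer", size = 2L),
    stop_hq(sprintf("unsupported NIfTI storage type '%s'", storage)))
}

#' Write a 3-D array as a NIfTI-1 volume
#'
#' @param data 3-D numeric array, indexed \[x, y, z\].
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @param spacing voxel size in mm per axis (length 3).
#' @param origin mm coordinate of the center of voxel \[1, 1, 1\] (length 3).
#' @param storage one of `"float32"`, `"int32"`, `"int16"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        storage = "float32") {
  stopifnot(length(dim(data)) == 3L, length(spacing) == 3L, length(origin) == 3L)
  dt <- nifti_dtype(storage)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(NIFTI_HDR_SIZE, 4L)                       # sizeof_hdr
  writeBin(raw(36), con)                       # data_type, db_name, extents, ...
  wi(c(3L, dim(data), 1L, 1L, 1L, 1L), 2L)     # dim[8]
  wf(c(0, 0, 0))                               # intent_p1..p3
  wi(0L, 2L)                                   # intent_code
  wi(dt$code, 2L)                              # datatype
  wi(dt$bitpix, 2L)                            # bitpix
  wi(0L, 2L)                                   # slice_start
  wf(c(1, spacing, 1, 1, 1, 1))                # pixdim[8]
  wf(NIFTI_VOX_OFFSET)                         # vox_offset
  wf(c(1, 0))                                  # scl_slope, scl_inter
  wi(0L, 2L); writeBin(raw(2), con)            # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0))                               # cal_max, cal_min, slice_duration
  wf(0)                                        # toffset
  wi(c(0L, 0L), 4L)                            # glmax, glmin
  writeBin(raw(104), con)                      # descrip[80] + aux_file[24]
  wi(c(0L, 1L), 2L)                            # qform_code, sform_code
  wf(c(0, 0, 0, 0, 0, 0))                      # quaternions
  wf(c(spacing[1], 0, 0, origin[1]))           # srow_x
  wf(c(0, spacing[2], 0, origin[2]))           # srow_y
  wf(c(0, 0, spacing[3], origin[3]))           # srow_z
  writeBin(raw(16), con)                       # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)   # magic
  writeBin(raw(4), con)                        # extension flag
  vec <- as.vector(data)
  if (dt$what == "integer") {
    writeBin(as.integer(round(vec)), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.numeric(vec), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume written by [write_nifti()] (or compatible)
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return list with `data` (3-D array), `spacing`, `origin`, `datatype`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop_hq(sprintf("file not found: %s", path))
  con <- gzfile(path, "rb")   # gzfile transparently reads uncompressed files
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = NIFTI_HDR_SIZE)
  if (length(hdr) < NIFTI_HDR_SIZE)
    stop_hq(sprintf("not a NIfTI-1 file (short header): %s", path))
  endian <- "little"
  if (readBin(hdr[1:4], "integer", size = 4L, endian = endian) != NIFTI_HDR_SIZE) {
    endian <- "big"
    if (readBin(hdr[1:4], "integer", size = 4L, endian = endian) != NIFTI_HDR_SIZE)
      stop_hq(sprintf("not a NIfTI-1 file (bad sizeof_hdr): %s", path))
  }
  ri <- function(off, n, size) readBin(hdr[(off + 1):(off + n * size)],
                                       "integer", n = n, size = size, endian = endian)
  rf <- function(off, n) readBin(hdr[(off + 1):(off + n * 4)],
                                 "numeric", n = n, size = 4L, endian = endian)
  dims <- ri(40L, 8L, 2L)
  if (dims[1] < 3L) stop_hq("only 3-D NIfTI volumes are supported")
  shp <- pmax(dims[2:4], 1L)
  datatype <- ri(70L, 1L, 2L)
  pixdim <- rf(76L, 8L)
  vox_offset <- rf(108L, 1L)
  slope <- rf(112L, 1L); inter <- rf(116L, 1L)
  sform_code <- ri(254L, 1L, 2L)
  srow <- rbind(rf(280L, 4L), rf(296L, 4L), rf(312L, 4L))
  spacing <- abs(pixdim[2:4])
  origin <- if (sform_code > 0L) srow[, 4] else c(0, 0, 0)
  if (sform_code > 0L) spacing <- sqrt(colSums(srow[, 1:3]^2))
  skip <- vox_offset - NIFTI_HDR_SIZE
  if (skip > 0) readBin(con, "raw", n = as.integer(skip))
  n <- prod(shp)
  vec <- switch(as.character(datatype),
    "16" = readBin(con, "numeric", n = n, size = 4L, endian = endian),
    "64" = readBin(con, "numeric", n = n, size = 8L, endian = endian),
    "8"  = readBin(con, "integer", n = n, size = 4L, endian = endian),
    "4"  = readBin(con, "integer", n = n, size = 2L, endian = endian),
    "2"  = readBin(con, "integer", n = n, size = 1L, signed = FALSE),
    stop_hq(sprintf("unsupported NIfTI datatype code %d in %s", datatype, path)))
  if (length(vec) < n) stop_hq(sprintf("truncated NIfTI data in %s", path))
  if (is.na(slope) || slope == 0) slope <- 1
  if (is.na(inter)) inter <- 0
  if (slope != 1 || inter != 0) vec <- vec * slope + inter
  list(data = array(vec, dim = shp), spacing = spacing, origin = origin,
       datatype = datatype)
}
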