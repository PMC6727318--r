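# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# Scope: 3D volumes, axis-aligned geometry only. The writer emits a
# diagonal sform (RAS convention per the NIfTI standard) encoding the
# package's LPS-mm frame; the reader accepts any diagonal sform (either
# axis polarity, flipping the array as needed) and refuses oblique
# volumes. float64 is the default on-disk type so that write -> read
# round-trips are bit-exact.

NIFTI_HDR_SIZE <- 348L
NIFTI_VOX_OFFSET <- 352L

nifti_dtypes <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE, bitpix = 8L),
  `4`  = list(what = "integer", size = 2L, signed = TRUE,  bitpix = 16L),
  `8`  = list(what = "integer", size = 4L, signed = TRUE,  bitpix = 32L),
  `16` = list(what = "double",  size = 4L, signed = TRUE,  bitpix = 32L),
  `64` = list(what = "double",  size = 8L, signed = TRUE,  bitpix = 64L)
)

open_maybe_gz <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a voxel grid as a NIfTI-1 volume
#'
#' @param grid a [voxel_grid] (or [binary_mask]; written as 0/1).
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param datatype on-disk type: `"float64"` (default, lossless for R
#'   doubles), `"float32"`, or `"int16"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path, datatype = c("float64", "float32", "int16")) {
  stopifnot(inherits(grid, "voxel_grid"))
  datatype <- match.arg(datatype)
  code <- switch(datatype, float64 = 64L, float32 = 16L, int16 = 4L)
  dt <- nifti_dtypes[[as.character(code)]]
  con <- open_maybe_gz(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)
  sp <- grid$spacing; or <- grid$origin; dm <- grid$dims

  w_i32(NIFTI_HDR_SIZE)                       # sizeof_hdr
  w_raw(36L)                                  # data_type..dim_info
  w_i16(c(3L, dm, 1L, 1L, 1L, 1L))            # dim[8]
  w_f32(c(0, 0, 0))                           # intent_p1..p3
  w_i16(0L)                                   # intent_code
  w_i16(code)                                 # datatype
  w_i16(dt$bitpix)                            # bitpix
  w_i16(0L)                                   # slice_start
  w_f32(c(1, sp, 1, 1, 1, 1))                 # pixdim[8] (qfac = 1)
  w_f32(NIFTI_VOX_OFFSET)                     # vox_offset
  w_f32(c(1, 0))                              # scl_slope, scl_inter
  w_i16(0L)                                   # slice_end
  writeBin(as.raw(c(0L, 2L)), con)            # slice_code, xyzt_units (mm)
  w_f32(c(0, 0, 0, 0))                        # cal_max..toffset
  w_i32(c(0L, 0L))                            # glmax, glmin
  # descrip carries full-precision LPS geometry (srow is only float32):
  # 6-byte tag + 6 little-endian doubles (origin, spacing)
  geo <- writeBin(c(or, sp), raw(), size = 8L, endian = "little")
  desc <- c(charToRaw("PQGEO1"), geo)
  w_raw_str <- function(s, n) writeBin(c(s, raw(n - length(s))), con)
  w_raw_str(desc, 80L)                        # descrip
  w_raw(24L)                                  # aux_file
  w_i16(c(0L, 1L))                            # qform_code = 0, sform_code = 1
  w_f32(c(0, 0, 0, 0, 0, 0))                  # quatern b,c,d + qoffset x,y,z
  # LPS -> RAS: negate x and y
  w_f32(c(-sp[1], 0, 0, -or[1]))              # srow_x
  w_f32(c(0, -sp[2], 0, -or[2]))              # srow_y
  w_f32(c(0, 0, sp[3], or[3]))                # srow_z
  w_raw(16L)                                  # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  w_raw(4L)                                   # pad to vox_offset 352

  vals <- grid$values
  if (is.logical(vals)) storage.mode(vals) <- "double"
  if (code == 4L) {
    v <- as.integer(round(vals))
    if (any(abs(vals - v) > 0.5, na.rm = TRUE) ||
        any(abs(v) > 32767, na.rm = TRUE))
      stop("values do not fit int16; use a float datatype")
    writeBin(v, con, size = 2L, endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

read_nifti_header <- function(con, endian) {
  r_i32 <- function(n) readBin(con, "integer", n, size = 4L, endian = endian)
  r_i16 <- function(n) readBin(con, "integer", n, size = 2L, endian = endian)
  r_f32 <- function(n) readBin(con, "double", n, size = 4L, endian = endian)
  hdr <- list()
  hdr$sizeof_hdr <- r_i32(1)
  readBin(con, "raw", 36L)
  hdr$dim <- r_i16(8)
  r_f32(3); r_i16(1)
  hdr$datatype <- r_i16(1)
  hdr$bitpix <- r_i16(1)
  r_i16(1)
  hdr$pixdim <- r_f32(8)
  hdr$vox_offset <- r_f32(1)
  hdr$scl_slope <- r_f32(1)
  hdr$scl_inter <- r_f32(1)
  r_i16(1); readBin(con, "raw", 2L)
  r_f32(4); r_i32(2)
  hdr$descrip <- readBin(con, "raw", 80L)
  readBin(con, "raw", 24L)                    # aux_file
  hdr$qform_code <- r_i16(1)
  hdr$sform_code <- r_i16(1)
  r_f32(6)
  hdr$srow <- matrix(r_f32(12), nrow = 3, byrow = TRUE)
  readBin(con, "raw", 16L)
  hdr$magic <- rawToChar(readBin(con, "raw", 3L))
  readBin(con, "raw", 1L)
  hdr
}

#' Read a volume into a voxel grid
#'
#' Core format is NIfTI-1 (`.nii`, `.nii.gz`), 3D, axis-aligned. Geometry
#' is converted to the package's LPS-mm world frame; values are returned
#' untouched apart from the NIfTI scale/intercept.
#'
#' @param path input file.
#' @param format only `"nifti"` is supported.
#' @return A [voxel_grid].
#' @export
read_volume <- function(path, format = "nifti") {
  format <- match.arg(format, "nifti")
  if (!file.exists(path)) stop("file not found: ", path)
  con <- open_maybe_gz(path, "rb")
  on.exit(close(con))
  endian <- "little"
  hdr <- read_nifti_header(con, endian)
  if (!identical(hdr$sizeof_hdr, NIFTI_HDR_SIZE)) {
    close(con); on.exit()
    con <- open_maybe_gz(path, "rb")
    on.exit(close(con))
    endian <- "big"
    hdr <- read_nifti_header(con, endian)
    if (!identical(hdr$sizeof_hdr, NIFTI_HDR_SIZE))
      stop("not a NIfTI-1 file (bad header size): ", path)
  }
  if (!hdr$magic %in% c("n+1", "ni1"))
    stop("not a NIfTI-1 file (bad magic): ", path)
  if (hdr$dim[1] != 3L)
    stop("only 3D NIfTI volumes are supported (dim[0] = ", hdr$dim[1], ")")
  dm <- hdr$dim[2:4]
  dt <- nifti_dtypes[[as.character(hdr$datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", hdr$datatype)

  # geometry: prefer the package's full-precision descrip record, then
  # the sform; either way the volume must be axis-aligned
  exact_geo <- NULL
  if (length(hdr$descrip) >= 54L &&
      identical(rawToChar(hdr$descrip[1:6]), "PQGEO1")) {
    g <- readBin(hdr$descrip[7:54], "double", 6L, size = 8L, endian = "little")
    if (all(is.finite(g)) && all(g[4:6] > 0))
      exact_geo <- list(origin = g[1:3], spacing = g[4:6])
  }
  if (hdr$sform_code > 0L) {
    m <- hdr$srow[, 1:3]
    offd <- m; diag(offd) <- 0
    if (any(abs(offd) > 1e-4 * max(abs(diag(m)))))
      stop("oblique-unsupported: non-axis-aligned sform in ", path)
    diagm <- diag(m)
    trans <- hdr$srow[, 4]
  } else {
    diagm <- c(-hdr$pixdim[2], -hdr$pixdim[3], hdr$pixdim[4])
    trans <- c(0, 0, 0)
  }
  if (any(diagm == 0)) stop("degenerate NIfTI affine in ", path)

  # data
  skip <- round(hdr$vox_offset) - NIFTI_HDR_SIZE
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(dm)
  vals <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) != n) stop("truncated NIfTI data in ", path)
  if (is.finite(hdr$scl_slope) && hdr$scl_slope != 0 &&
      !(hdr$scl_slope == 1 && hdr$scl_inter == 0))
    vals <- vals * hdr$scl_slope + hdr$scl_inter
  arr <- array(as.numeric(vals), dm)

  if (!is.null(exact_geo))  # written by this package: already LPS, no flips
    return(voxel_grid(arr, origin = exact_geo$origin,
                      spacing = exact_geo$spacing))

  # RAS -> LPS (negate x, y), flipping axes so spacing is positive
  lps_sign <- c(-1, -1, 1)
  origin <- numeric(3)
  spacing <- numeric(3)
  for (a in 1:3) {
    m <- lps_sign[a] * diagm[a]
    t <- lps_sign[a] * trans[a]
    if (m > 0) {
      spacing[a] <- m
      origin[a] <- t
    } else {
      spacing[a] <- -m
      origin[a] <- t + m * (dm[a] - 1)
      idx <- rev(seq_len(dm[a]))
      arr <- switch(a, arr[idx, , , drop = FALSE],
                    arr[, idx, , drop = FALSE], arr[, , idx, drop = FALSE])
    }
  }
  voxel_grid(arr, origin = origin, spacing = spacing)
}

#' Read a dose distribution
#'
#' Reads a NIfTI dose volume (Gy) plus its isocenter, supplied either
#' directly or through a YAML sidecar (`<path minus .nii[.gz]>.yaml`, key
#' `isocenter_mm: [x, y, z]`).
#'
#' @param path NIfTI dose file.
#' @param format only `"nifti"`.
#' @param isocenter numeric length 3 (mm), overrides the sidecar.
#' @param sidecar explicit sidecar path (default derived from `path`).
#' @return A [dose_grid].
#' @export
read_dose <- function(path, format = "nifti", isocenter = NULL, sidecar = NULL) {
  grid <- read_volume(path, format)
  if (any(grid$values < 0))
    stop("negative dose values in ", path)
  if (is.null(isocenter)) {
    if (is.null(sidecar))
      sidecar <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".yaml")
    if (!file.exists(sidecar))
      stop("no isocenter given and sidecar not found: ", sidecar)
    y <- yaml::read_yaml(sidecar)
    if (is.null(y$isocenter_mm))
      stop("sidecar lacks `isocenter_mm`: ", sidecar)
    isocenter <- as.numeric(y$isocenter_mm)
  }
  dose_grid(grid, isocenter)
}

#' Write a dose distribution (NIfTI volume + YAML isocenter sidecar)
#'
#' @param dose a [dose_grid].
#' @param path NIfTI output path.
#' @param sidecar sidecar path (default derived from `path`).
#' @return `path`, invisibly.
#' @export
write_dose <- function(dose, path, sidecar = NULL) {
  stopifnot(inherits(dose, "dose_grid"))
  write_volume(dose$grid, path)
  if (is.null(sidecar))
    sidecar <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".yaml")
  yaml::write_yaml(list(isocenter_mm = as.numeric(dose$isocenter)), sidecar)
  invisible(path)
}
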