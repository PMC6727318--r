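# Domain containers. All geometry lives in DICOM-style LPS world
# coordinates, millimetres. Grids are axis-aligned; `origin` is the world
# position of the CENTER of voxel (0,0,0); world(i,j,k) = origin + index *
# spacing with 0-based continuous indices.

#' Axis-aligned 3D voxel grid
#'
#' The basic container for CT images (HU) and dose distributions (Gy).
#' Values are stored in a 3D array; geometry is an axis-aligned affine
#' (no rotation): the world position of 0-based voxel index `(i,j,k)` is
#' `origin + c(i,j,k) * spacing`, in LPS millimetres. The bounding box
#' extends half a voxel beyond the extreme voxel centers.
#'
#' @param values 3D numeric array.
#' @param origin numeric length 3; world position (mm) of the center of
#'   voxel `(0,0,0)`.
#' @param spacing numeric length 3; voxel pitch in mm, strictly positive.
#' @return An object of class `voxel_grid` with fields `values`, `origin`,
#'   `spacing`, `dims`, `frame`.
#' @examples
#' g <- voxel_grid(array(0, c(4, 4, 4)), origin = c(0, 0, 0),
#'                 spacing = c(2, 2, 2))
#' index_to_world(g, c(1, 1, 1))
#' @export
voxel_grid <- function(values, origin = c(0, 0, 0), spacing = c(1, 1, 1)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  origin <- as.numeric(origin)
  spacing <- as.numeric(spacing)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be a finite 3-vector (mm)")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be a strictly positive 3-vector (mm)")
  storage.mode(values) <- "double"
  structure(list(values = values, origin = origin, spacing = spacing,
                 dims = dim(values), frame = "LPS-mm"),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, spacing (%g, %g, %g) mm, origin (%g, %g, %g) [%s]\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3], x$frame))
  invisible(x)
}

#' Dose grid: a voxel grid of dose in Gy plus a plan isocenter
#'
#' @param grid [voxel_grid] with non-negative dose values (Gy).
#' @param isocenter numeric length 3, mm; must lie inside the grid
#'   bounding box (voxel centers extended by half a voxel).
#' @return Object of class `dose_grid` with fields `grid`, `isocenter`.
#' @export
dose_grid <- function(grid, isocenter) {
  stopifnot(inherits(grid, "voxel_grid"))
  isocenter <- as.numeric(isocenter)
  if (length(isocenter) != 3L || any(!is.finite(isocenter)))
    stop("`isocenter` must be a finite 3-vector (mm)")
  if (any(grid$values < 0, na.rm = TRUE))
    stop("dose values must be non-negative (Gy)")
  lo <- grid$origin - grid$spacing / 2
  hi <- grid$origin + (grid$dims - 1) * grid$spacing + grid$spacing / 2
  if (any(isocenter < lo) || any(isocenter > hi))
    stop("isocenter lies outside the dose grid bounding box")
  structure(list(grid = grid, isocenter = isocenter), class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> isocenter (%g, %g, %g) mm, max %.4g Gy\n",
              x$isocenter[1], x$isocenter[2], x$isocenter[3],
              max(x$grid$values)))
  print(x$grid)
  invisible(x)
}

#' Fiducial marker point set
#'
#' Implanted gold seed positions in LPS millimetres, as localized either on
#' MRI-derived data or on the QA-CT.
#'
#' @param points numeric matrix, one row per marker, 3 columns (x, y, z mm).
#' @param labels character vector of unique marker labels.
#' @param modality `"MRI"` or `"CT"`.
#' @return Object of class `fiducial_set`.
#' @export
fiducial_set <- function(points, labels = NULL, modality = c("CT", "MRI")) {
  modality <- match.arg(modality)
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("`points` must have 3 columns (x, y, z mm)")
  n <- nrow(points)
  if (n < 3L) stop("at least 3 markers required")
  if (is.null(labels)) labels <- paste0("M", seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n || anyDuplicated(labels))
    stop("labels must be unique, one per marker")
  if (any(!is.finite(points))) stop("marker coordinates must be finite")
  d <- as.matrix(stats::dist(points))
  diag(d) <- Inf
  if (min(d) < 1e-6)
    stop("two markers closer than 1e-6 mm: degenerate set")
  rownames(points) <- labels
  colnames(points) <- c("x_mm", "y_mm", "z_mm")
  structure(list(points = points, labels = labels, modality = modality),
            class = "fiducial_set")
}

#' @export
print.fiducial_set <- function(x, ...) {
  cat(sprintf("<fiducial_set> %d markers (%s)\n", nrow(x$points), x$modality))
  print(round(x$points, 3))
  invisible(x)
}

#' Gamma evaluation criteria
#'
#' Dose-difference / distance-to-agreement criteria for the 3D gamma index,
#' plus the low-dose threshold and normalization convention.
#'
#' @param dose_diff_pct dose-difference criterion, percent (e.g. 2).
#' @param dta_mm distance-to-agreement criterion, mm (e.g. 2).
#' @param low_dose_threshold_fraction voxels whose reference dose is below
#'   this fraction of the maximum reference dose are excluded (default 0.20).
#' @param normalization `"global_max_ref"` (default; dose differences
#'   normalized by the maximum reference dose in the mask) or `"local"`
#'   (by the local reference dose).
#' @param search_step_mm sub-voxel search lattice pitch, mm. `NULL` means
#'   "choose at evaluation time": `min(spacing)/3` capped at `dta_mm/2`.
#' @return Object of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dose_diff_pct, dta_mm,
                           low_dose_threshold_fraction = 0.20,
                           normalization = c("global_max_ref", "local"),
                           search_step_mm = NULL) {
  normalization <- match.arg(normalization)
  stopifnot(dose_diff_pct > 0, dta_mm > 0,
            low_dose_threshold_fraction >= 0, low_dose_threshold_fraction < 1)
  if (!is.null(search_step_mm)) {
    stopifnot(search_step_mm > 0)
    if (search_step_mm > dta_mm)
      stop("search_step_mm must not exceed dta_mm")
  }
  structure(list(dose_diff_pct = dose_diff_pct, dta_mm = dta_mm,
                 low_dose_threshold_fraction = low_dose_threshold_fraction,
                 normalization = normalization,
                 search_step_mm = search_step_mm),
            class = "gamma_criteria")
}

#' @export
print.gamma_criteria <- function(x, ...) {
  cat(sprintf("<gamma_criteria> %g%%/%g mm, threshold %g, %s normalization\n",
              x$dose_diff_pct, x$dta_mm, x$low_dose_threshold_fraction,
              x$normalization))
  invisible(x)
}

#' QA tolerances for the MRI-only plan checklist
#'
#' All numeric thresholds of the verification procedure in one place:
#' isocenter dose agreement, gamma pass-rate acceptance, fiducial
#' distance-to-centroid tolerance, skin exclusion margin, and the common
#' resampling lattice pitch.
#'
#' @param iso_dose_pct isocenter dose agreement tolerance, percent.
#' @param gamma_pass_pct minimum acceptable gamma pass-rate, percent
#'   (acceptance requires pass-rate strictly greater than this).
#' @param fiducial_tol_mm marker distance-to-centroid tolerance, mm.
#' @param skin_margin_mm per-slice 2D erosion margin excluding the skin
#'   region, mm.
#' @param resample_mm isotropic comparison lattice pitch, mm.
#' @return Object of class `qa_tolerances`.
#' @export
qa_tolerances <- function(iso_dose_pct = 2.0, gamma_pass_pct = 90.0,
                          fiducial_tol_mm = 1.0, skin_margin_mm = 20.0,
                          resample_mm = 1.5) {
  vals <- c(iso_dose_pct, gamma_pass_pct, fiducial_tol_mm,
            skin_margin_mm, resample_mm)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all tolerances must be strictly positive")
  structure(list(iso_dose_pct = iso_dose_pct, gamma_pass_pct = gamma_pass_pct,
                 fiducial_tol_mm = fiducial_tol_mm,
                 skin_margin_mm = skin_margin_mm, resample_mm = resample_mm),
            class = "qa_tolerances")
}

#' Binary mask on a voxel grid
#'
#' Same geometry as an associated [voxel_grid] but logical values.
#'
#' @param values 3D logical array.
#' @param origin,spacing grid geometry, as for [voxel_grid].
#' @return Object of class `binary_mask`.
#' @export
binary_mask <- function(values, origin = c(0, 0, 0), spacing = c(1, 1, 1)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (!is.logical(values)) {
    if (!all(values %in% c(0, 1, NA)))
      stop("mask values must be logical or 0/1")
    values <- array(as.logical(values), dim(values))
  }
  values[is.na(values)] <- FALSE
  g <- structure(list(values = values, origin = as.numeric(origin),
                      spacing = as.numeric(spacing), dims = dim(values),
                      frame = "LPS-mm"),
                 class = c("binary_mask", "voxel_grid"))
  if (any(g$spacing <= 0)) stop("spacing must be strictly positive")
  g
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d / %d voxels set\n",
              sum(x$values), prod(x$dims)))
  NextMethod()
}

# shared geometry check used by mask/grid algebra
same_geometry <- function(a, b, tol = 1e-6) {
  all(a$dims == b$dims) &&
    all(abs(a$origin - b$origin) < tol) &&
    all(abs(a$spacing - b$spacing) < tol)
}

#' World/index coordinate transforms
#'
#' `world_to_index()` maps world points (mm) to continuous 0-based voxel
#' indices; `index_to_world()` is its inverse. Neither clamps: indices may
#' lie outside `[0, dims - 1]`.
#'
#' @param grid a [voxel_grid].
#' @param p numeric length 3, or an n x 3 matrix of points.
#' @return Numeric of the same shape as `p`.
#' @export
world_to_index <- function(grid, p) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (is.matrix(p))
    sweep(sweep(p, 2, grid$origin), 2, grid$spacing, "/")
  else
    (as.numeric(p) - grid$origin) / grid$spacing
}

#' @rdname world_to_index
#' @export
index_to_world <- function(grid, p) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (is.matrix(p))
    sweep(sweep(p, 2, grid$spacing, "*"), 2, grid$origin, "+")
  else
    grid$origin + as.numeric(p) * grid$spacing
}

#' Trilinear interpolation of a voxel grid at world points
#'
#' Exact at voxel centers; linear in between. Points may lie up to half a
#' voxel outside the extreme voxel centers (clamped); beyond that the
#' "outside-grid" condition is signalled.
#'
#' @param grid a [voxel_grid].
#' @param p numeric length 3 (mm) or an n x 3 matrix of world points.
#' @param outside `"error"` (default) to signal an error for points outside
#'   the bounding box, or `"na"` to return `NA` there.
#' @return Numeric vector of sampled values.
#' @export
sample_trilinear <- function(grid, p, outside = c("error", "na")) {
  outside <- match.arg(outside)
  stopifnot(inherits(grid, "voxel_grid"))
  pts <- if (is.matrix(p)) p else matrix(as.numeric(p), nrow = 1)
  vals <- grid$values
  if (is.logical(vals)) storage.mode(vals) <- "double"
  out <- cpp_sample_trilinear(as.numeric(vals), as.integer(grid$dims),
                              grid$origin, grid$spacing, pts, TRUE)
  if (outside == "error" && anyNA(out)) {
    bad <- which(is.na(out))[1]
    stop(sprintf("outside-grid: point (%g, %g, %g) lies outside the grid bounding box",
                 pts[bad, 1], pts[bad, 2], pts[bad, 3]))
  }
  out
}
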