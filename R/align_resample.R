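# Isocenter alignment and resampling of a dose pair onto one common
# isotropic lattice before comparison.

#' Align the evaluated dose to the reference by isocenter translation
#'
#' Translation-only alignment: the evaluated grid's origin is shifted by
#' `ref$isocenter - eval$isocenter` so the two isocenters coincide. Values
#' are untouched.
#'
#' @param ref,eval_dose [dose_grid] objects (reference: QA-CT
#'   recalculation; evaluated: pseudo-CT plan).
#' @return The translated evaluated [dose_grid].
#' @export
align_by_isocenter <- function(ref, eval_dose) {
  stopifnot(inherits(ref, "dose_grid"), inherits(eval_dose, "dose_grid"))
  shift <- ref$isocenter - eval_dose$isocenter
  g <- eval_dose$grid
  g$origin <- g$origin + shift
  dose_grid(g, ref$isocenter)
}

#' Resample an aligned dose pair onto a shared isotropic lattice
#'
#' The shared lattice has isotropic pitch `spacing_mm`, covers the
#' intersection of the two grids' voxel-center bounding boxes, and is
#' anchored so the reference isocenter falls exactly on a lattice point
#' (the isocenter dose then reads a stored, not interpolated, value).
#' Both doses are trilinearly interpolated onto it; no extrapolation.
#'
#' @param ref reference [dose_grid].
#' @param eval_dose evaluated [dose_grid], already isocenter-aligned.
#' @param spacing_mm isotropic lattice pitch, mm (default 1.5).
#' @return List with `ref` and `eval` [dose_grid]s on identical geometry.
#' @export
resample_pair_to_common <- function(ref, eval_dose, spacing_mm = 1.5) {
  stopifnot(inherits(ref, "dose_grid"), inherits(eval_dose, "dose_grid"),
            spacing_mm > 0)
  if (max(abs(ref$isocenter - eval_dose$isocenter)) > 1e-6)
    stop("dose grids must be isocenter-aligned first (see align_by_isocenter)")
  ga <- ref$grid; gb <- eval_dose$grid
  lo <- pmax(ga$origin, gb$origin)
  hi <- pmin(ga$origin + (ga$dims - 1) * ga$spacing,
             gb$origin + (gb$dims - 1) * gb$spacing)
  if (any(lo > hi)) stop("no overlap between the two dose grids")
  iso <- ref$isocenter
  # lattice points iso + k * spacing inside [lo, hi], per axis
  k_lo <- ceiling((lo - iso) / spacing_mm - 1e-9)
  k_hi <- floor((hi - iso) / spacing_mm + 1e-9)
  if (any(k_lo > k_hi)) stop("no overlap between the two dose grids")
  origin <- iso + k_lo * spacing_mm
  dims <- as.integer(k_hi - k_lo + 1)

  coords <- lapply(1:3, function(a) origin[a] + (seq_len(dims[a]) - 1) * spacing_mm)
  pts <- as.matrix(expand.grid(coords[[1]], coords[[2]], coords[[3]],
                               KEEP.OUT.ATTRS = FALSE))
  resamp <- function(g) {
    v <- sample_trilinear(g, pts, outside = "na")
    # lattice is inside both center boxes by construction; NA would mean a
    # geometry bug, not a data condition
    if (anyNA(v)) stop("internal error: resample point left the source grid")
    voxel_grid(array(v, dims), origin = origin, spacing = rep(spacing_mm, 3))
  }
  list(ref = dose_grid(resamp(ga), iso), eval = dose_grid(resamp(gb), iso))
}

#' Resample a binary mask onto a target lattice
#'
#' Trilinear interpolation of the 0/1 field, thresholded at 0.5. Points
#' outside the mask's grid count as background.
#'
#' @param mask a [binary_mask].
#' @param target a [voxel_grid] (or [dose_grid]) defining the lattice.
#' @return A [binary_mask] on the target geometry.
#' @export
resample_mask_to <- function(mask, target) {
  stopifnot(inherits(mask, "binary_mask"))
  if (inherits(target, "dose_grid")) target <- target$grid
  stopifnot(inherits(target, "voxel_grid"))
  coords <- lapply(1:3, function(a)
    target$origin[a] + (seq_len(target$dims[a]) - 1) * target$spacing[a])
  pts <- as.matrix(expand.grid(coords[[1]], coords[[2]], coords[[3]],
                               KEEP.OUT.ATTRS = FALSE))
  src <- voxel_grid(array(as.numeric(mask$values), mask$dims),
                    origin = mask$origin, spacing = mask$spacing)
  v <- sample_trilinear(src, pts, outside = "na")
  v[is.na(v)] <- 0
  binary_mask(array(v >= 0.5, target$dims), origin = target$origin,
              spacing = target$spacing)
}
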