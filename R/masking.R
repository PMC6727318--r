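# Construction of the gamma evaluation mask: body contour from the QA-CT,
# minus a skin margin applied as an independent 2D erosion on each axial
# plane, intersected with the low-dose threshold region.

#' Extract the patient body mask from a CT volume
#'
#' Thresholds the image, keeps the largest 3D connected component
#' (26-connectivity), and fills internal cavities slice by slice, so air
#' pockets (rectal gas) stay inside the body.
#'
#' @param image a [voxel_grid] of HU values.
#' @param hu_threshold voxels strictly above this HU count as tissue
#'   (default -300, the usual external-contour cut between air and soft
#'   tissue).
#' @return A [binary_mask].
#' @export
extract_body_mask <- function(image, hu_threshold = -300) {
  stopifnot(inherits(image, "voxel_grid"))
  fg <- image$values > hu_threshold
  if (!any(fg)) stop("empty body mask: no voxels above ", hu_threshold, " HU")
  if (all(fg)) stop("body mask covers the whole grid: no air background")
  cc <- cpp_largest_cc(as.logical(fg), as.integer(image$dims))
  filled <- cpp_fill_holes_2d(cc, as.integer(image$dims))
  binary_mask(array(filled, image$dims), origin = image$origin,
              spacing = image$spacing)
}

#' Erode a mask in 2D, slice by slice
#'
#' Each axial (xy) slice is independently eroded by a discrete disk whose
#' radius is `round(margin_mm / in-plane spacing)` voxels; slices never
#' influence each other. This removes a skin margin where the external
#' contours of CT and pseudo-CT disagree.
#'
#' @param mask a [binary_mask].
#' @param margin_mm erosion margin, mm (default 20); 0 is the identity.
#' @return The eroded [binary_mask] (possibly empty).
#' @export
erode_mask_2d <- function(mask, margin_mm = 20.0) {
  stopifnot(inherits(mask, "binary_mask"), margin_mm >= 0)
  if (margin_mm == 0) return(mask)
  sp <- mask$spacing[1:2]
  if (abs(sp[1] - sp[2]) > 1e-6 * max(sp))
    stop("2D erosion requires isotropic in-plane spacing, got ",
         sp[1], " x ", sp[2], " mm")
  r_vox <- round(margin_mm / sp[1])
  if (r_vox == 0) return(mask)
  out <- cpp_erode2d(as.logical(mask$values), as.integer(mask$dims), r_vox)
  binary_mask(array(out, mask$dims), origin = mask$origin,
              spacing = mask$spacing)
}

#' Dilate a mask in 2D, slice by slice
#'
#' Counterpart of [erode_mask_2d()], used e.g. to add an external "skin"
#' shell to a body contour.
#'
#' @inheritParams erode_mask_2d
#' @return The dilated [binary_mask].
#' @export
dilate_mask_2d <- function(mask, margin_mm) {
  stopifnot(inherits(mask, "binary_mask"), margin_mm >= 0)
  if (margin_mm == 0) return(mask)
  sp <- mask$spacing[1:2]
  if (abs(sp[1] - sp[2]) > 1e-6 * max(sp))
    stop("2D dilation requires isotropic in-plane spacing")
  r_vox <- round(margin_mm / sp[1])
  if (r_vox == 0) return(mask)
  out <- cpp_dilate2d(as.logical(mask$values), as.integer(mask$dims), r_vox)
  binary_mask(array(out, mask$dims), origin = mask$origin,
              spacing = mask$spacing)
}

#' Low-dose threshold mask
#'
#' True where the reference dose is at least `fraction` of its maximum;
#' the threshold is always computed from the reference (QA-CT) dose.
#'
#' @param ref reference [dose_grid].
#' @param fraction threshold fraction of the maximum dose (default 0.20).
#'   At `fraction = 0` every voxel satisfies dose >= 0, so the mask is
#'   all-true.
#' @return A [binary_mask] on the reference geometry.
#' @export
low_dose_threshold_mask <- function(ref, fraction = 0.20) {
  stopifnot(inherits(ref, "dose_grid"), fraction >= 0, fraction < 1)
  dmax <- max(ref$grid$values)
  if (dmax <= 0) stop("all-zero reference dose: threshold undefined")
  binary_mask(ref$grid$values >= fraction * dmax,
              origin = ref$grid$origin, spacing = ref$grid$spacing)
}

#' Combine body, skin-eroded, and dose-threshold masks
#'
#' Voxelwise AND of the eroded body mask and the dose-threshold mask.
#' (The un-eroded body mask is accepted for interface completeness and
#' checked for geometry, but the eroded mask is by construction a subset
#' of it.)
#'
#' @param body full body [binary_mask].
#' @param eroded skin-eroded body [binary_mask].
#' @param dose_mask low-dose threshold [binary_mask].
#' @return The evaluation [binary_mask]. Warns when empty.
#' @export
evaluation_mask <- function(body, eroded, dose_mask) {
  for (m in list(body, eroded, dose_mask))
    stopifnot(inherits(m, "binary_mask"))
  if (!same_geometry(body, eroded) || !same_geometry(body, dose_mask))
    stop("mask geometry mismatch")
  out <- eroded$values & dose_mask$values
  if (!any(out))
    warning("evaluation mask is empty: gamma will report n_evaluated = 0")
  binary_mask(out, origin = body$origin, spacing = body$spacing)
}
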