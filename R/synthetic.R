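# Self-contained synthetic test cases: a digital pelvis CT (elliptic body,
# femoral heads, pelvic ring, prostate, optional rectal gas), pseudo-CT
# perturbation modes (tissue/bone HU bias, an external 1 mm "skin" shell,
# boundary jitter), a toy ray-traced dose engine, and jittered fiducial
# sets — every pipeline stage gets a ground truth.

#' Specification of the digital pelvis phantom
#'
#' Default anatomy: an elliptic-cylinder body of soft tissue (0 HU,
#' semi-axes 180 x 120 mm, length 200 mm) in air (-1000 HU), two femoral
#' head spheres (radius 22 mm, +700 HU), an elliptic pelvic ring annulus
#' (+500 HU), a prostate sphere (radius 22 mm, +30 HU) at the isocenter,
#' and an optional rectal air cavity (-1000 HU) posterior to the prostate.
#'
#' @param body_semiaxes_mm in-plane body semi-axes (x, y), mm.
#' @param body_length_mm superior-inferior body extent, mm.
#' @param spacing_mm voxel spacing, mm (scalar or length 3).
#' @param femhead_radius_mm,femhead_offset_mm femoral head geometry.
#' @param ring_outer_mm,ring_inner_mm pelvic ring annulus semi-axes.
#' @param ring_length_mm annulus superior-inferior extent.
#' @param prostate_radius_mm prostate sphere radius.
#' @param rectum set `TRUE` for a rectal air cavity.
#' @param air_margin_mm air padding around the body, mm.
#' @param seed integer; stored for downstream seeded perturbations.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(body_semiaxes_mm = c(180, 120),
                         body_length_mm = 200,
                         spacing_mm = 2.5,
                         femhead_radius_mm = 22,
                         femhead_offset_mm = 110,
                         ring_outer_mm = c(110, 80),
                         ring_inner_mm = c(90, 60),
                         ring_length_mm = 120,
                         prostate_radius_mm = 22,
                         rectum = TRUE,
                         air_margin_mm = 15,
                         seed = 1L) {
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3)
  stopifnot(all(body_semiaxes_mm > 0), body_length_mm > 0,
            all(spacing_mm > 0), femhead_radius_mm > 0,
            prostate_radius_mm > 0, air_margin_mm >= 0)
  structure(as.list(environment()), class = "phantom_spec")
}

#' Pseudo-CT perturbation specification
#'
#' Controllable discrepancy modes between the pseudo-CT and the ground
#' truth CT: a HU bias in soft tissue, a HU bias in bone, an external
#' soft-tissue "skin" shell added by per-slice 2D dilation of the body
#' contour (1.0 mm emulates the early algorithm variant whose erroneous
#' layer was later dropped), random per-slice contour jitter, and
#' isotropic Gaussian jitter of the MRI fiducial positions.
#'
#' @param tissue_hu_bias HU offset inside the body excluding bone.
#' @param bone_hu_bias HU offset in bone.
#' @param skin_layer_mm thickness of the added external shell, mm
#'   (default 0; 1.0 reproduces the legacy variant).
#' @param contour_jitter_mm amplitude of random per-slice body-contour
#'   erosion/dilation, mm.
#' @param fiducial_sigma_mm isotropic Gaussian jitter per marker
#'   coordinate, mm.
#' @param seed integer seed for the stochastic components.
#' @return A `perturbation_spec`.
#' @export
perturbation_spec <- function(tissue_hu_bias = 0, bone_hu_bias = 0,
                              skin_layer_mm = 0, contour_jitter_mm = 0,
                              fiducial_sigma_mm = 0, seed = 1L) {
  stopifnot(skin_layer_mm >= 0, contour_jitter_mm >= 0,
            fiducial_sigma_mm >= 0)
  structure(as.list(environment()), class = "perturbation_spec")
}

#' Beam arrangement and toy dose-engine parameters
#'
#' Emulates a 7-field IMRT-style arrangement: `n_beams` equispaced gantry
#' angles in the axial plane, each a broad beam with a smooth aperture
#' profile, exponentially attenuated with water-equivalent path length.
#'
#' @param n_beams number of equispaced beams (default 7).
#' @param half_width_mm in-plane aperture half-width, mm.
#' @param z_half_mm superior-inferior aperture half-extent, mm.
#' @param penumbra_mm Gaussian penumbra width of the aperture edge, mm.
#' @param prescription_gy dose at the isocenter after scaling, Gy
#'   (default 2, one fraction).
#' @param mu_per_mm effective linear attenuation coefficient per mm of
#'   water-equivalent depth (default 0.005/mm, megavoltage-like).
#' @return A `beam_spec`.
#' @export
beam_spec <- function(n_beams = 7L, half_width_mm = 35, z_half_mm = 35,
                      penumbra_mm = 3, prescription_gy = 2.0,
                      mu_per_mm = 0.005) {
  stopifnot(n_beams >= 1, half_width_mm > 0, z_half_mm > 0,
            penumbra_mm > 0, prescription_gy > 0, mu_per_mm > 0)
  structure(as.list(environment()), class = "beam_spec")
}

#' Build the digital pelvis phantom
#'
#' Deterministic for a given spec. Three fiducial markers are placed at
#' fixed offsets (~10 mm) from the prostate center, forming a
#' non-degenerate triangle with pairwise separations >= 5 mm; the
#' isocenter is the prostate center.
#'
#' @param spec a [phantom_spec].
#' @return List: `ct` ([voxel_grid], HU), `masks` (list of [binary_mask]:
#'   `body`, `bone`, `prostate`), `fiducials_ct` ([fiducial_set]),
#'   `isocenter` (mm).
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  sp <- spec$spacing_mm
  half <- c(spec$body_semiaxes_mm + spec$air_margin_mm,
            spec$body_length_mm / 2 + spec$air_margin_mm)
  dims <- as.integer(2 * ceiling(half / sp) + 1)
  origin <- -(dims - 1) / 2 * sp  # grid centered on (0,0,0)
  xs <- origin[1] + (seq_len(dims[1]) - 1) * sp[1]
  ys <- origin[2] + (seq_len(dims[2]) - 1) * sp[2]
  zs <- origin[3] + (seq_len(dims[3]) - 1) * sp[3]
  X <- array(rep(xs, times = dims[2] * dims[3]), dims)
  Y <- array(rep(rep(ys, each = dims[1]), times = dims[3]), dims)
  Z <- array(rep(zs, each = dims[1] * dims[2]), dims)

  a <- spec$body_semiaxes_mm[1]; b <- spec$body_semiaxes_mm[2]
  body <- (X / a)^2 + (Y / b)^2 <= 1 & abs(Z) <= spec$body_length_mm / 2
  if (!any(body)) stop("phantom body does not intersect the grid")

  sphere <- function(cx, cy, cz, r)
    (X - cx)^2 + (Y - cy)^2 + (Z - cz)^2 <= r^2
  fem1 <- sphere(-spec$femhead_offset_mm, 0, 0, spec$femhead_radius_mm)
  fem2 <- sphere(spec$femhead_offset_mm, 0, 0, spec$femhead_radius_mm)
  ring <- (X / spec$ring_outer_mm[1])^2 + (Y / spec$ring_outer_mm[2])^2 <= 1 &
          (X / spec$ring_inner_mm[1])^2 + (Y / spec$ring_inner_mm[2])^2 >= 1 &
          abs(Z) <= spec$ring_length_mm / 2
  bone <- (fem1 | fem2 | ring) & body
  prostate <- sphere(0, 0, 0, spec$prostate_radius_mm) & body
  if (any(fem1 & !body) || any(fem2 & !body))
    stop("femoral heads extend outside the body")

  hu <- array(-1000, dims)
  hu[body] <- 0
  hu[bone] <- ifelse((fem1 | fem2)[bone], 700, 500)
  hu[prostate & !bone] <- 30
  if (isTRUE(spec$rectum)) {
    rect <- sphere(0, 45, 0, 14) & body
    hu[rect & !bone] <- -1000
  }

  fid_off <- rbind(c(9, 0, -5), c(-7, 6, 4), c(-2, -8, 6))
  fiducials <- fiducial_set(fid_off, labels = c("F1", "F2", "F3"),
                            modality = "CT")
  list(ct = voxel_grid(hu, origin = origin, spacing = sp),
       masks = list(body = binary_mask(body, origin, sp),
                    bone = binary_mask(bone, origin, sp),
                    prostate = binary_mask(prostate, origin, sp)),
       fiducials_ct = fiducials,
       isocenter = c(0, 0, 0))
}

#' Derive a perturbed pseudo-CT from the phantom CT
#'
#' Applies the discrepancy modes of a [perturbation_spec] to the ground
#' truth CT: per-tissue-class HU biases, an optional external soft-tissue
#' shell (per-slice 2D dilation of the body contour by `skin_layer_mm`),
#' and optional seeded per-slice contour jitter.
#'
#' @param ct phantom CT ([voxel_grid]).
#' @param masks mask list from [make_phantom()].
#' @param perturb a [perturbation_spec].
#' @return The pseudo-CT [voxel_grid].
#' @export
make_pseudo_ct <- function(ct, masks, perturb = perturbation_spec()) {
  stopifnot(inherits(ct, "voxel_grid"), inherits(perturb, "perturbation_spec"))
  if (!same_geometry(ct, masks$body)) stop("mask geometry mismatch")
  hu <- ct$values
  body <- masks$body$values
  bone <- masks$bone$values
  soft <- body & !bone
  hu[soft] <- hu[soft] + perturb$tissue_hu_bias
  hu[bone] <- hu[bone] + perturb$bone_hu_bias

  if (perturb$contour_jitter_mm > 0) {
    set.seed(perturb$seed)
    r_vox <- round(perturb$contour_jitter_mm / ct$spacing[1])
    if (r_vox > 0) {
      bodyj <- body
      for (k in seq_len(ct$dims[3])) {
        mode <- sample(c(-1L, 0L, 1L), 1)
        if (mode == 0L) next
        slice <- binary_mask(array(body[, , k], c(ct$dims[1:2], 1L)),
                             origin = ct$origin, spacing = ct$spacing)
        slice <- if (mode > 0)
          dilate_mask_2d(slice, perturb$contour_jitter_mm)
        else erode_mask_2d(slice, perturb$contour_jitter_mm)
        newb <- slice$values[, , 1]
        gained <- newb & !body[, , k]
        lost <- body[, , k] & !newb
        huk <- hu[, , k]
        huk[gained] <- perturb$tissue_hu_bias  # new soft tissue
        huk[lost] <- -1000
        hu[, , k] <- huk
        bodyj[, , k] <- newb
      }
      body <- bodyj
    }
  }

  if (perturb$skin_layer_mm > 0) {
    shell_src <- binary_mask(body, ct$origin, ct$spacing)
    dilated <- dilate_mask_2d(shell_src, perturb$skin_layer_mm)
    shell <- dilated$values & !body
    hu[shell] <- 0  # added external layer reads as soft tissue
  }
  voxel_grid(hu, origin = ct$origin, spacing = ct$spacing)
}

#' Toy dose engine: ray-traced exponential attenuation
#'
#' HU are mapped to relative electron density by the standard calibration
#' linearization `rho = 1 + HU/1000` (clipped to `[0, 2]`). Each beam
#' contributes `profile * exp(-mu_eff * WEPL)` where WEPL is the
#' density-weighted ray integral from the surface along the beam axis
#' (step `min(spacing)/2`, trilinear density sampling) and the profile is
#' a smooth (erfc-edged) aperture in both the in-plane and
#' superior-inferior directions. Beams are summed and globally scaled so
#' the isocenter receives the prescription dose. Deliberately simple — no
#' scatter, no buildup — but direction-correct for QA exercises.
#'
#' @param image CT or pseudo-CT [voxel_grid] (HU).
#' @param beams a [beam_spec].
#' @param isocenter numeric length 3, mm; must lie inside the body (HU
#'   above -300 at the isocenter).
#' @param dose_grid_geom optional [voxel_grid] defining the output dose
#'   lattice; defaults to the image lattice.
#' @param scale optional fixed output scaling (Gy per unit raw engine
#'   output). `NULL` (default) normalizes so the isocenter receives the
#'   prescription — planning mode. Passing the `scale` attribute of a
#'   previously planned dose emulates recalculating with the same
#'   fluences and monitor units on another image.
#' @return A [dose_grid] in Gy, with the applied scaling in its `scale`
#'   attribute.
#' @export
toy_dose_engine <- function(image, beams = beam_spec(), isocenter,
                            dose_grid_geom = NULL, scale = NULL) {
  stopifnot(inherits(image, "voxel_grid"), inherits(beams, "beam_spec"))
  isocenter <- as.numeric(isocenter)
  hu_iso <- sample_trilinear(image, isocenter)
  if (hu_iso <= -300)
    stop("isocenter lies outside the body (HU ", round(hu_iso), ")")
  tgt <- if (is.null(dose_grid_geom)) image else dose_grid_geom
  angles <- 2 * pi * (seq_len(beams$n_beams) - 1) / beams$n_beams
  step <- min(image$spacing) / 2
  raw <- cpp_raytrace_dose(as.numeric(image$values), as.integer(image$dims),
                           image$origin, image$spacing,
                           as.integer(tgt$dims), tgt$origin, tgt$spacing,
                           isocenter, angles, beams$mu_per_mm,
                           beams$half_width_mm, beams$z_half_mm,
                           beams$penumbra_mm, step)
  arr <- array(raw, tgt$dims)
  g <- voxel_grid(arr, origin = tgt$origin, spacing = tgt$spacing)
  if (is.null(scale)) {
    d_iso <- sample_trilinear(g, isocenter)
    if (d_iso <= 0) stop("zero dose at isocenter: beam geometry error")
    scale <- beams$prescription_gy / d_iso
  }
  g$values <- g$values * scale
  out <- dose_grid(g, isocenter)
  attr(out, "scale") <- scale
  out
}

#' Generate a complete synthetic QA case
#'
#' Builds the phantom, derives the perturbed pseudo-CT, runs the toy dose
#' engine on both volumes with the same beam arrangement (the reference
#' dose on the ground-truth CT, the evaluated dose on the pseudo-CT),
#' applies seeded Gaussian jitter to produce the MRI fiducial set, and
#' sets all manual checklist flags true. The injected ground truth is
#' stored in the bundle's `truth` field.
#'
#' @param spec a [phantom_spec].
#' @param perturb a [perturbation_spec].
#' @param beams a [beam_spec].
#' @param case_id identifier string.
#' @return A [case_bundle].
#' @export
make_case <- function(spec = phantom_spec(), perturb = perturbation_spec(),
                      beams = beam_spec(), case_id = "synthetic") {
  ph <- make_phantom(spec)
  pct <- make_pseudo_ct(ph$ct, ph$masks, perturb)
  # the plan is made (and normalized) on the pseudo-CT; the QA-CT
  # recalculation reuses the same fluences/monitor units, i.e. the same
  # raw-to-Gy scale
  ev <- toy_dose_engine(pct, beams, ph$isocenter)
  ref <- toy_dose_engine(ph$ct, beams, ph$isocenter,
                         scale = attr(ev, "scale"))
  set.seed(perturb$seed + 1L)
  jitter <- if (perturb$fiducial_sigma_mm > 0)
    matrix(stats::rnorm(9, sd = perturb$fiducial_sigma_mm), 3, 3)
  else matrix(0, 3, 3)
  fid_mri <- fiducial_set(ph$fiducials_ct$points + jitter,
                          labels = ph$fiducials_ct$labels, modality = "MRI")
  flags <- default_manual_flags()
  flags[] <- TRUE
  case_bundle(ct = ph$ct, pseudo_ct = pct, ref_dose = ref, eval_dose = ev,
              fiducials_mri = fid_mri, fiducials_ct = ph$fiducials_ct,
              manual_flags = flags, case_id = case_id,
              truth = list(spec = spec, perturb = perturb, beams = beams,
                           fiducial_jitter = jitter))
}
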