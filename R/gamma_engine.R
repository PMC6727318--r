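# 3D gamma index between a reference (QA-CT) and an evaluated (pseudo-CT)
# dose on a shared lattice, plus the isocenter dose check.

resolve_step <- function(criteria, spacing) {
  step <- criteria$search_step_mm
  if (is.null(step)) step <- min(min(spacing) / 3, criteria$dta_mm / 2)
  min(step, criteria$dta_mm)
}

gamma_common <- function(ref, eval_dose, criteria, mask, engine_fn) {
  stopifnot(inherits(ref, "dose_grid"), inherits(eval_dose, "dose_grid"),
            inherits(criteria, "gamma_criteria"), inherits(mask, "binary_mask"))
  ga <- ref$grid; gb <- eval_dose$grid
  if (!same_geometry(ga, gb) || !same_geometry(ga, mask))
    stop("reference, evaluated dose and mask must share one lattice ",
         "(use resample_pair_to_common)")
  msk <- as.logical(mask$values)
  n_eval <- sum(msk)
  dims <- as.integer(ga$dims)
  if (n_eval == 0L) {
    warning("empty evaluation mask: gamma undefined (n_evaluated = 0)")
    gmap <- voxel_grid(array(NA_real_, dims), ga$origin, ga$spacing)
    return(structure(list(pass_rate_pct = NA_real_, mean_gamma = NA_real_,
                          gamma_map = gmap, n_evaluated = 0L,
                          n_edge_limited = 0L, criteria = criteria),
                     class = "gamma_result"))
  }
  dnorm <- max(ga$values[msk])
  if (criteria$normalization == "global_max_ref" && dnorm <= 0)
    stop("maximum reference dose in the mask is zero: normalization undefined")
  if (criteria$normalization == "local" && any(ga$values[msk] <= 0))
    stop("local normalization requires strictly positive reference dose in the mask")
  step <- resolve_step(criteria, ga$spacing)
  res <- engine_fn(as.numeric(ga$values), as.numeric(gb$values), dims,
                   ga$spacing, msk, criteria$dose_diff_pct, criteria$dta_mm,
                   step, dnorm, criteria$normalization == "local")
  gvals <- res$gamma
  gmap <- voxel_grid(array(gvals, dims), ga$origin, ga$spacing)
  attr(gmap, "edge_limited") <- array(res$edge, dims)
  gm <- gvals[msk]
  # gamma <= 1 passes (inclusive); 1e-9 guard so exact-boundary cases are
  # not tipped by floating-point round-off
  structure(list(
    pass_rate_pct = 100 * sum(gm <= 1 + 1e-9) / n_eval,
    mean_gamma = mean(gm),
    gamma_map = gmap,
    n_evaluated = n_eval,
    n_edge_limited = sum(res$edge),
    criteria = criteria
  ), class = "gamma_result")
}

#' 3D gamma index evaluation
#'
#' For each masked reference voxel `r`, the gamma index is the minimum over
#' candidate points `r'` of
#' `sqrt(((D_eval(r') - D_ref(r)) / (delta/100 * D_norm))^2 + (|r' - r| / DTA)^2)`,
#' where `D_norm` is the maximum reference dose within the mask (global
#' normalization, the default) or the local reference dose. Candidates
#' form a cubic lattice of pitch `criteria$search_step_mm` centered on `r`
#' (radius `3 * DTA`), with the evaluated dose sampled trilinearly; the
#' search is pruned adaptively (a candidate whose distance term alone
#' exceeds the current best gamma cannot improve it). A voxel passes when
#' gamma <= 1 (inclusive).
#'
#' Reference voxels whose search neighborhood extends beyond the evaluated
#' grid are computed over the available candidates and flagged in the
#' `edge_limited` attribute of the gamma map. (Under pruning the flag is
#' raised only when a candidate that could still have improved the result
#' fell outside the grid; candidates already excluded by the distance
#' bound are irrelevant to the minimum.)
#'
#' @param ref,eval_dose [dose_grid]s on one shared lattice (see
#'   [resample_pair_to_common()]).
#' @param criteria a [gamma_criteria].
#' @param mask evaluation [binary_mask] on the same lattice.
#' @return A `gamma_result`: `pass_rate_pct`, `mean_gamma` (over all
#'   evaluated voxels), `gamma_map` ([voxel_grid], `NA` outside the mask),
#'   `n_evaluated`, `n_edge_limited`, `criteria`.
#' @export
compute_gamma <- function(ref, eval_dose, criteria, mask) {
  gamma_common(ref, eval_dose, criteria, mask, cpp_gamma_engine)
}

#' Exhaustive gamma oracle
#'
#' Independent brute-force implementation for verification: enumerates the
#' full candidate lattice with no pruning. Same lattice definition as
#' [compute_gamma()], so the two agree to floating point. Small grids only.
#'
#' @inheritParams compute_gamma
#' @return A `gamma_result`.
#' @export
gamma_oracle <- function(ref, eval_dose, criteria, mask) {
  gamma_common(ref, eval_dose, criteria, mask, cpp_gamma_oracle)
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %g%%/%g mm: pass %.1f%%, mean gamma %.3f (n = %d%s)\n",
              x$criteria$dose_diff_pct, x$criteria$dta_mm,
              x$pass_rate_pct, x$mean_gamma, x$n_evaluated,
              if (x$n_edge_limited > 0)
                sprintf(", %d edge-limited", x$n_edge_limited) else ""))
  invisible(x)
}

#' Isocenter dose comparison
#'
#' Samples both doses trilinearly at the (shared) isocenter and compares
#' them: `diff_pct = 100 * (eval - ref) / ref`, passing when
#' `|diff_pct| <= tol_pct` (boundary inclusive).
#'
#' @param ref,eval_dose isocenter-aligned [dose_grid]s.
#' @param tol_pct tolerance, percent (default 2).
#' @return An `iso_dose_check`: `ref_dose_gy`, `eval_dose_gy`, `diff_pct`,
#'   `tolerance_pct`, `passed`.
#' @export
isocenter_dose_check <- function(ref, eval_dose, tol_pct = 2.0) {
  stopifnot(inherits(ref, "dose_grid"), inherits(eval_dose, "dose_grid"),
            tol_pct > 0)
  if (max(abs(ref$isocenter - eval_dose$isocenter)) > 1e-6)
    stop("isocenters must coincide (align first)")
  dref <- sample_trilinear(ref$grid, ref$isocenter)
  deval <- sample_trilinear(eval_dose$grid, ref$isocenter)
  if (dref <= 0) stop("reference dose at isocenter is not positive")
  diff_pct <- 100 * (deval - dref) / dref
  # inclusive boundary, with an epsilon so FP round-off cannot tip an
  # exactly-at-tolerance case
  structure(list(ref_dose_gy = dref, eval_dose_gy = deval,
                 diff_pct = diff_pct, tolerance_pct = tol_pct,
                 passed = abs(diff_pct) <= tol_pct + 1e-9),
            class = "iso_dose_check")
}

#' @export
print.iso_dose_check <- function(x, ...) {
  cat(sprintf("<iso_dose_check> ref %.4g Gy, eval %.4g Gy: %+.2f%% (tol %.1f%%) %s\n",
              x$ref_dose_gy, x$eval_dose_gy, x$diff_pct, x$tolerance_pct,
              if (x$passed) "PASS" else "FAIL"))
  invisible(x)
}
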