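# Case-level QA pipeline and checklist report, plus cohort summaries.

#' Bundle everything needed to QA one case
#'
#' Mirrors what the planning system holds at QA time: the QA-CT and
#' pseudo-CT images, the dose recalculated on the QA-CT (reference) and
#' the plan dose on the pseudo-CT (evaluated), both fiducial sets, and the
#' operator's visual checklist flags.
#'
#' @param ct,pseudo_ct [voxel_grid]s of HU.
#' @param ref_dose,eval_dose [dose_grid]s.
#' @param fiducials_mri,fiducials_ct [fiducial_set]s of equal cardinality.
#' @param manual_flags named logical vector over the six visual checklist
#'   items (`NA` = not assessed); see [default_manual_flags()].
#' @param case_id string identifier.
#' @param truth optional list of ground-truth generator parameters
#'   (synthetic cases).
#' @return A `case_bundle`.
#' @export
case_bundle <- function(ct, pseudo_ct, ref_dose, eval_dose,
                        fiducials_mri, fiducials_ct,
                        manual_flags = default_manual_flags(),
                        case_id = "case", truth = NULL) {
  stopifnot(inherits(ct, "voxel_grid"), inherits(pseudo_ct, "voxel_grid"),
            inherits(ref_dose, "dose_grid"), inherits(eval_dose, "dose_grid"),
            inherits(fiducials_mri, "fiducial_set"),
            inherits(fiducials_ct, "fiducial_set"))
  if (nrow(fiducials_mri$points) != nrow(fiducials_ct$points))
    stop("fiducial sets must have equal cardinality")
  flags <- default_manual_flags()
  for (nm in names(manual_flags))
    if (nm %in% names(flags)) flags[[nm]] <- manual_flags[[nm]]
  structure(list(ct = ct, pseudo_ct = pseudo_ct, ref_dose = ref_dose,
                 eval_dose = eval_dose, fiducials_mri = fiducials_mri,
                 fiducials_ct = fiducials_ct, manual_flags = flags,
                 case_id = as.character(case_id), truth = truth),
            class = "case_bundle")
}

checklist_row <- function(label, kind, status, evidence = NULL) {
  list(label = label, kind = kind, status = status, evidence = evidence)
}

#' Run the full QA pipeline for one case
#'
#' Executes: isocenter alignment, resampling of both doses onto the
#' common isotropic lattice, body-mask extraction from the QA-CT with
#' per-slice skin-margin erosion, low-dose thresholding, gamma evaluation
#' for every criteria set, the isocenter dose check, and the fiducial
#' distance-to-centroid check; then fills the nine-row QA checklist. The
#' three automated rows draw on the computed evidence (the "Dose
#' distribution" row uses the 2%/2 mm gamma result); the six visual rows
#' come from the bundle's `manual_flags`, with unassessed items blocking
#' the overall pass. A stage failure marks the affected rows failed and
#' records the error; no exception escapes without a report.
#'
#' @param bundle a [case_bundle].
#' @param tolerances a [qa_tolerances].
#' @param criteria_list list of [gamma_criteria] (default: 3%/3 mm,
#'   2%/2 mm, 2%/1 mm).
#' @return A `qa_report`: `case_id`, `checklist` (nine ordered rows),
#'   `gamma_results`, `iso_check`, `fiducial_result`, `overall_pass`,
#'   `errors`.
#' @export
run_case_qa <- function(bundle, tolerances = qa_tolerances(),
                        criteria_list = default_criteria_list()) {
  stopifnot(inherits(bundle, "case_bundle"), inherits(tolerances, "qa_tolerances"))
  errors <- list()
  note <- function(stage, e) errors[[stage]] <<- conditionMessage(e)

  gamma_results <- list()
  iso_check <- NULL
  fiducial_result <- NULL

  tryCatch({
    aligned <- align_by_isocenter(bundle$ref_dose, bundle$eval_dose)
    pair <- resample_pair_to_common(bundle$ref_dose, aligned,
                                    spacing_mm = tolerances$resample_mm)
    body <- extract_body_mask(bundle$ct)
    eroded <- erode_mask_2d(body, tolerances$skin_margin_mm)
    eroded_l <- resample_mask_to(eroded, pair$ref)
    body_l <- resample_mask_to(body, pair$ref)
    dose_mask <- low_dose_threshold_mask(
      pair$ref, criteria_list[[1]]$low_dose_threshold_fraction)
    emask <- evaluation_mask(body_l, eroded_l, dose_mask)
    for (cr in criteria_list) {
      key <- sprintf("%g%%/%gmm", cr$dose_diff_pct, cr$dta_mm)
      gamma_results[[key]] <- compute_gamma(pair$ref, pair$eval, cr, emask)
    }
    iso_check <- isocenter_dose_check(pair$ref, pair$eval,
                                      tolerances$iso_dose_pct)
  }, error = function(e) note("dose_comparison", e))

  fiducial_result <- tryCatch(
    fiducial_qa(bundle$fiducials_mri, bundle$fiducials_ct,
                tolerances$fiducial_tol_mm),
    error = function(e) { note("fiducial_qa", e); NULL })

  # -- checklist -------------------------------------------------------
  checklist <- list()
  for (item in MANUAL_CHECKLIST_ITEMS) {
    flag <- bundle$manual_flags[[item]]
    status <- if (is.na(flag)) "not_assessed" else if (flag) "pass" else "fail"
    checklist[[item]] <- checklist_row(item, "manual", status,
                                       evidence = "operator flag")
  }

  if (!is.null(iso_check)) {
    checklist[["Dose at isocenter"]] <- checklist_row(
      "Dose at isocenter", "automated",
      if (iso_check$passed) "pass" else "fail",
      evidence = list(diff_pct = iso_check$diff_pct,
                      tolerance_pct = iso_check$tolerance_pct))
  } else {
    checklist[["Dose at isocenter"]] <- checklist_row(
      "Dose at isocenter", "automated", "fail",
      evidence = list(error = errors$dose_comparison))
  }

  key22 <- vapply(gamma_results, function(g)
    g$criteria$dose_diff_pct == 2 && g$criteria$dta_mm == 2, logical(1))
  g22 <- if (any(key22)) gamma_results[[which(key22)[1]]]
         else if (length(gamma_results)) gamma_results[[1]] else NULL
  if (!is.null(g22) && !is.na(g22$pass_rate_pct)) {
    checklist[["Dose distribution"]] <- checklist_row(
      "Dose distribution", "automated",
      if (g22$pass_rate_pct > tolerances$gamma_pass_pct) "pass" else "fail",
      evidence = list(criteria = sprintf("%g%%/%g mm", g22$criteria$dose_diff_pct,
                                         g22$criteria$dta_mm),
                      pass_rate_pct = g22$pass_rate_pct,
                      mean_gamma = g22$mean_gamma,
                      required_pct = tolerances$gamma_pass_pct))
  } else {
    checklist[["Dose distribution"]] <- checklist_row(
      "Dose distribution", "automated", "fail",
      evidence = list(error = if (is.null(g22)) errors$dose_comparison
                      else "empty evaluation mask"))
  }

  if (!is.null(fiducial_result) && inherits(fiducial_result, "fiducial_qa_result")) {
    checklist[["Fiducial marker positions"]] <- checklist_row(
      "Fiducial marker positions", "automated",
      if (fiducial_result$passed) "pass" else "fail",
      evidence = list(max_abs_diff_mm = fiducial_result$max_abs_diff_mm,
                      rms_diff_mm = fiducial_result$rms_diff_mm,
                      tolerance_mm = fiducial_result$tolerance_mm))
  } else {
    checklist[["Fiducial marker positions"]] <- checklist_row(
      "Fiducial marker positions", "automated", "fail",
      evidence = list(error = errors$fiducial_qa))
    fiducial_result <- NULL
  }

  order_all <- c(MANUAL_CHECKLIST_ITEMS, AUTOMATED_CHECKLIST_ITEMS)
  checklist <- checklist[order_all]

  statuses <- vapply(checklist, function(r) r$status, character(1))
  structure(list(case_id = bundle$case_id, checklist = checklist,
                 gamma_results = gamma_results, iso_check = iso_check,
                 fiducial_result = fiducial_result,
                 overall_pass = all(statuses == "pass"),
                 errors = errors),
            class = "qa_report")
}

#' @export
print.qa_report <- function(x, ...) {
  cat(sprintf("QA report for %s: %s\n", x$case_id,
              if (x$overall_pass) "PASS" else "FAIL"))
  cat(format_report_text(x), sep = "\n")
  invisible(x)
}

format_report_text <- function(report) {
  lines <- c(sprintf("Case: %s", report$case_id),
             sprintf("Overall: %s", if (report$overall_pass) "PASS" else "FAIL"),
             "")
  marks <- c(pass = "✓", fail = "✗", not_assessed = "?")
  for (row in report$checklist) {
    ev <- row$evidence
    ev_txt <- if (is.character(ev)) ev
      else paste(vapply(names(ev), function(n) {
        v <- ev[[n]]
        if (is.numeric(v)) sprintf("%s=%.4g", n, v) else sprintf("%s=%s", n, v)
      }, character(1)), collapse = ", ")
    lines <- c(lines, sprintf("[%s] %-28s (%s) %s", marks[[row$status]],
                              row$label, row$kind, ev_txt))
  }
  lines
}

report_to_list <- function(report) {
  list(
    case_id = report$case_id,
    overall_pass = report$overall_pass,
    checklist = lapply(unname(report$checklist), function(r)
      list(label = r$label, kind = r$kind, status = r$status,
           evidence = r$evidence)),
    gamma = lapply(report$gamma_results, function(g)
      list(dose_diff_pct = g$criteria$dose_diff_pct,
           dta_mm = g$criteria$dta_mm,
           pass_rate_pct = g$pass_rate_pct, mean_gamma = g$mean_gamma,
           n_evaluated = g$n_evaluated, n_edge_limited = g$n_edge_limited)),
    iso_check = if (!is.null(report$iso_check))
      report$iso_check[c("ref_dose_gy", "eval_dose_gy", "diff_pct",
                         "tolerance_pct", "passed")],
    fiducials = if (!is.null(report$fiducial_result))
      list(per_marker = report$fiducial_result$per_marker,
           max_abs_diff_mm = report$fiducial_result$max_abs_diff_mm,
           rms_diff_mm = report$fiducial_result$rms_diff_mm,
           tolerance_mm = report$fiducial_result$tolerance_mm,
           passed = report$fiducial_result$passed),
    errors = report$errors
  )
}

#' Summarize a cohort of per-case scalars
#'
#' Mean, sample (n-1) standard deviation, Bland-Altman limits of agreement
#' (mean +/- 1.96 sd), root-mean-square, and range — the statistics used
#' to report isocenter dose differences and fiducial distance differences
#' across a patient cohort.
#'
#' @param values numeric vector, length >= 2.
#' @param metric_name label carried in the summary.
#' @return A `cohort_summary` list.
#' @export
summarize_cohort <- function(values, metric_name = "metric") {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("cohort summary requires n >= 2")
  if (any(!is.finite(values))) stop("non-finite values in cohort")
  m <- mean(values)
  s <- stats::sd(values)
  structure(list(metric = metric_name, n = length(values), mean = m, sd = s,
                 loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
                 rms = sqrt(mean(values^2)),
                 min = min(values), max = max(values)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %s (n = %d): mean %.4g, sd %.4g, LoA [%.4g, %.4g], rms %.4g, range [%.4g, %.4g]\n",
              x$metric, x$n, x$mean, x$sd, x$loa_low, x$loa_high, x$rms,
              x$min, x$max))
  invisible(x)
}

#' Summarize a list of QA reports into cohort statistics
#'
#' Aggregates isocenter dose differences, gamma pass-rates and mean gamma
#' per criteria set, and pooled fiducial distance differences, each as a
#' [summarize_cohort()] row.
#'
#' @param reports list of `qa_report` objects.
#' @return A data.frame, one row per metric.
#' @export
summarize_cohort_reports <- function(reports) {
  stopifnot(length(reports) >= 2L)
  out <- list()
  iso <- vapply(reports, function(r) r$iso_check$diff_pct, numeric(1))
  out[["iso_diff_pct"]] <- summarize_cohort(iso, "isocenter dose difference (%)")
  keys <- names(reports[[1]]$gamma_results)
  for (k in keys) {
    pr <- vapply(reports, function(r) r$gamma_results[[k]]$pass_rate_pct, numeric(1))
    mg <- vapply(reports, function(r) r$gamma_results[[k]]$mean_gamma, numeric(1))
    out[[paste0("gamma_pass_", k)]] <- summarize_cohort(pr, paste("gamma pass-rate (%)", k))
    out[[paste0("mean_gamma_", k)]] <- summarize_cohort(mg, paste("mean gamma", k))
  }
  fid <- unlist(lapply(reports, function(r) r$fiducial_result$per_marker$diff_mm))
  out[["fiducial_diff_mm"]] <- summarize_cohort(fid, "fiducial distance difference (mm)")
  do.call(rbind, lapply(out, function(s)
    data.frame(metric = s$metric, n = s$n, mean = s$mean, sd = s$sd,
               loa_low = s$loa_low, loa_high = s$loa_high, rms = s$rms,
               min = s$min, max = s$max, stringsAsFactors = FALSE)))
}
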