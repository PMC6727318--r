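# CSV fiducials, YAML configuration, QA report serialization, and
# on-disk case bundles (NIfTI volumes + CSV point sets + YAML sidecars).

#' Read a fiducial marker set from CSV
#'
#' Dialect: comma-separated, UTF-8, decimal point, header
#' `label,x_mm,y_mm,z_mm,modality`. The clinical procedure records marker
#' coordinates in a spreadsheet; CSV is the archival analogue.
#'
#' @param path CSV file.
#' @return A [fiducial_set].
#' @export
read_fiducials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "x_mm", "y_mm", "z_mm", "modality")
  if (!all(need %in% names(df)))
    stop("fiducial CSV must have columns ", paste(need, collapse = ","))
  if (nrow(df) < 3L) stop("at least 3 markers required, got ", nrow(df))
  if (anyDuplicated(df$label)) stop("duplicate fiducial labels in ", path)
  modality <- unique(df$modality)
  if (length(modality) != 1L || !modality %in% c("MRI", "CT"))
    stop("fiducial CSV must carry a single modality, MRI or CT")
  fiducial_set(as.matrix(df[, c("x_mm", "y_mm", "z_mm")]),
               labels = df$label, modality = modality)
}

#' Write a fiducial marker set to CSV
#'
#' @param set a [fiducial_set].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fiducials <- function(set, path) {
  stopifnot(inherits(set, "fiducial_set"))
  df <- data.frame(label = set$labels,
                   x_mm = set$points[, 1], y_mm = set$points[, 2],
                   z_mm = set$points[, 3], modality = set$modality)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# The six visual checklist items a human must judge; the remaining three
# rows are computed. Order mirrors the clinical checklist.
MANUAL_CHECKLIST_ITEMS <- c(
  "Distortion correction",
  "Image transfer",
  "Image orientation and appearance",
  "Field of view",
  "Fiducial marker visibility",
  "Femoral heads"
)

AUTOMATED_CHECKLIST_ITEMS <- c(
  "Dose at isocenter",
  "Dose distribution",
  "Fiducial marker positions"
)

#' Default manual checklist flags ("not assessed")
#'
#' Visual checklist items are human judgments supplied via configuration;
#' unset items block an overall pass.
#' @return Named logical vector (all `NA`).
#' @export
default_manual_flags <- function() {
  flags <- rep(NA, length(MANUAL_CHECKLIST_ITEMS))
  names(flags) <- MANUAL_CHECKLIST_ITEMS
  flags
}

#' Read a QA configuration (tolerances, gamma criteria, manual flags)
#'
#' YAML schema: `tolerances:` ([qa_tolerances] fields), `criteria:` (list
#' of [gamma_criteria] field sets), `manual_flags:` (checklist item label
#' to true/false).
#'
#' @param path YAML file.
#' @return List with `tolerances`, `criteria`, `manual_flags`.
#' @export
read_qa_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  y <- yaml::read_yaml(path)
  tol <- do.call(qa_tolerances, as.list(y$tolerances))
  criteria <- if (is.null(y$criteria)) default_criteria_list()
              else lapply(y$criteria, function(cr) do.call(gamma_criteria, as.list(cr)))
  flags <- default_manual_flags()
  if (!is.null(y$manual_flags)) {
    unknown <- setdiff(names(y$manual_flags), names(flags))
    if (length(unknown))
      stop("unknown manual checklist item(s): ", paste(unknown, collapse = ", "))
    for (nm in names(y$manual_flags)) flags[[nm]] <- isTRUE(y$manual_flags[[nm]])
  }
  list(tolerances = tol, criteria = criteria, manual_flags = flags)
}

#' The three gamma criteria of the verification protocol
#'
#' 3%/3 mm, 2%/2 mm and 2%/1 mm, each with a 20% low-dose threshold and
#' global normalization.
#' @return List of [gamma_criteria].
#' @export
default_criteria_list <- function() {
  list(gamma_criteria(3, 3), gamma_criteria(2, 2), gamma_criteria(2, 1))
}

#' Serialize a QA report
#'
#' JSON form is a deterministic, machine-readable rendering of the full
#' report; text form prints each checklist row with a pass/fail mark and
#' its numeric evidence.
#'
#' @param report a `qa_report` (see [run_case_qa()]).
#' @param path output path.
#' @param format `"json"` or `"text"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "text")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "qa_report"))
  if (format == "json") {
    jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null", na = "null")
  } else {
    writeLines(format_report_text(report), path)
  }
  invisible(path)
}

#' Read back a JSON QA report
#'
#' @param path JSON file written by [write_report()].
#' @return A list mirroring the report structure.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a case bundle to a directory
#'
#' Lays out a complete case on disk: NIfTI CT and pseudo-CT, NIfTI dose
#' pair with YAML isocenter sidecars, CSV fiducial sets, and a YAML case
#' file with the manual flags.
#'
#' @param bundle a [case_bundle].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_case_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "case_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(bundle$ct, file.path(dir, "ct.nii"))
  write_volume(bundle$pseudo_ct, file.path(dir, "pseudo_ct.nii"))
  write_dose(bundle$ref_dose, file.path(dir, "ref_dose.nii"))
  write_dose(bundle$eval_dose, file.path(dir, "eval_dose.nii"))
  write_fiducials(bundle$fiducials_ct, file.path(dir, "fiducials_ct.csv"))
  write_fiducials(bundle$fiducials_mri, file.path(dir, "fiducials_mri.csv"))
  flags <- as.list(bundle$manual_flags)
  flags <- lapply(flags, function(f) if (is.na(f)) NULL else f)
  yaml::write_yaml(list(case_id = bundle$case_id, manual_flags = flags),
                   file.path(dir, "case.yaml"))
  invisible(dir)
}

#' Read a case bundle from a directory written by [write_case_bundle()]
#'
#' @param dir case directory.
#' @return A [case_bundle].
#' @export
read_case_bundle <- function(dir) {
  y <- yaml::read_yaml(file.path(dir, "case.yaml"))
  flags <- default_manual_flags()
  for (nm in names(y$manual_flags))
    if (nm %in% names(flags)) flags[[nm]] <- isTRUE(y$manual_flags[[nm]])
  case_bundle(
    ct = read_volume(file.path(dir, "ct.nii")),
    pseudo_ct = read_volume(file.path(dir, "pseudo_ct.nii")),
    ref_dose = read_dose(file.path(dir, "ref_dose.nii")),
    eval_dose = read_dose(file.path(dir, "eval_dose.nii")),
    fiducials_mri = read_fiducials(file.path(dir, "fiducials_mri.csv")),
    fiducials_ct = read_fiducials(file.path(dir, "fiducials_ct.csv")),
    manual_flags = flags,
    case_id = if (is.null(y$case_id)) basename(dir) else y$case_id
  )
}
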