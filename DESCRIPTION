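Package: planqa
Title: Quality Assurance for MRI-Only Radiotherapy Treatment Plans
Version: 0.1.0
Authors@R:
    person("planqa", "developers", email = "planqa@example.org", role = c("aut", "cre"))
Description: Plan quality assurance for MRI-only (pseudo-CT based) prostate
    radiotherapy. Implements the dosimetric verification workflow used when a
    conventional QA-CT is still acquired alongside an MRI-only plan: isocenter
    alignment and resampling of dose grids to a common lattice, body-contour
    masking with a two-dimensional per-slice skin-margin erosion, a 3D gamma
    index evaluation (dose difference / distance-to-agreement) with a low-dose
    threshold, an isocenter dose comparison, and a rigid-invariant fiducial
    marker distance-to-centroid check. A synthetic pelvis phantom and a toy
    ray-traced dose engine provide fully self-contained, ground-truthed test
    cases, and cohort summaries (Bland-Altman limits of agreement, gamma
    statistics) aggregate per-case reports.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
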