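# Fiducial marker QA: compare each marker's distance to the marker-set
# centroid between MRI-derived and QA-CT localizations. Distances to the
# centroid are invariant under rigid motion, so the check tolerates
# prostate rotation/translation between scans while catching size or
# localization errors.

#' Centroid of a fiducial set
#'
#' @param set a [fiducial_set] (>= 3 points).
#' @return Numeric length 3 (mm): the arithmetic mean of the marker
#'   coordinates.
#' @export
centroid <- function(set) {
  stopifnot(inherits(set, "fiducial_set"))
  colMeans(set$points)
}

permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Match markers between two fiducial sets
#'
#' The two scans live in different patient poses, so matching must use
#' only rigid-invariant intra-set geometry: the permutation of `b` is
#' chosen to minimize the sum of squared discrepancies between the two
#' sets' pairwise inter-marker distance matrices (exhaustive over the `n!`
#' permutations, `n <= 6`). Ties are broken toward the lexicographically
#' first label sequence of `b`.
#'
#' @param a,b [fiducial_set]s of equal cardinality.
#' @return Integer vector `m` with `a` marker `i` corresponding to `b`
#'   marker `m[i]`; labels as names.
#' @export
match_markers <- function(a, b) {
  stopifnot(inherits(a, "fiducial_set"), inherits(b, "fiducial_set"))
  n <- nrow(a$points)
  if (n != nrow(b$points))
    stop("fiducial sets have unequal cardinality (", n, " vs ",
         nrow(b$points), ")")
  if (n > 6L) stop("exhaustive matching supports at most 6 markers")
  da <- as.matrix(stats::dist(a$points))
  db <- as.matrix(stats::dist(b$points))
  perms <- permutations(n)
  cost <- apply(perms, 1, function(p)
    sum((da - db[p, p, drop = FALSE])^2) / 2)
  best <- which(cost <= min(cost) + 1e-12)
  if (length(best) > 1L) {  # deterministic tie-break: label order of b
    keys <- apply(perms[best, , drop = FALSE], 1,
                  function(p) paste(b$labels[p], collapse = "\r"))
    best <- best[order(keys)[1]]
  }
  m <- perms[best[1], ]
  names(m) <- a$labels
  m
}

#' Fiducial marker distance-to-centroid QA
#'
#' For each corresponded marker, computes its distance to the set centroid
#' in each modality and the signed difference `d_MRI - d_CT`. The check
#' passes when every `|difference| <= tol_mm` (boundary inclusive).
#' Because distances to the centroid are preserved by any rigid transform,
#' a pure rotation/translation between scans yields all differences zero.
#'
#' @param mri MRI-derived [fiducial_set].
#' @param ct QA-CT [fiducial_set].
#' @param tol_mm per-marker tolerance, mm (default 1.0).
#' @return A `fiducial_qa_result` with a per-marker table (`label`,
#'   `d_mri_mm`, `d_ct_mm`, `diff_mm`), `max_abs_diff_mm`, `rms_diff_mm`,
#'   `tolerance_mm`, `passed`, and the `correspondence` used.
#' @export
fiducial_qa <- function(mri, ct, tol_mm = 1.0) {
  stopifnot(inherits(mri, "fiducial_set"), inherits(ct, "fiducial_set"),
            tol_mm > 0)
  m <- match_markers(mri, ct)
  c_mri <- centroid(mri)
  c_ct <- centroid(ct)
  d_mri <- sqrt(rowSums(sweep(mri$points, 2, c_mri)^2))
  d_ct_all <- sqrt(rowSums(sweep(ct$points, 2, c_ct)^2))
  d_ct <- d_ct_all[m]
  diff <- d_mri - d_ct
  tab <- data.frame(label = mri$labels, ct_label = ct$labels[m],
                    d_mri_mm = as.numeric(d_mri),
                    d_ct_mm = as.numeric(d_ct),
                    diff_mm = as.numeric(diff),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(per_marker = tab,
                 max_abs_diff_mm = max(abs(diff)),
                 rms_diff_mm = sqrt(mean(diff^2)),
                 tolerance_mm = tol_mm,
                 passed = all(abs(diff) <= tol_mm),
                 correspondence = m),
            class = "fiducial_qa_result")
}

#' @export
print.fiducial_qa_result <- function(x, ...) {
  cat(sprintf("<fiducial_qa_result> max |diff| %.3f mm, rms %.3f mm (tol %.2f mm) %s\n",
              x$max_abs_diff_mm, x$rms_diff_mm, x$tolerance_mm,
              if (x$passed) "PASS" else "FAIL"))
  print(x$per_marker, digits = 4)
  invisible(x)
}
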