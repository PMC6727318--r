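tri_set <- function(modality = "CT")
  fiducial_set(rbind(c(0, 0, 0), c(30, 0, 0), c(0, 30, 0)),
               labels = c("F1", "F2", "F3"), modality = modality)

test_that("centroid is the coordinate mean and translation-equivariant", {
  s <- fiducial_set(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0)),
                    modality = "CT")
  expect_equal(unname(centroid(s)), c(1, 1, 0))
  set.seed(12)
  t <- rnorm(3, sd = 20)
  s2 <- fiducial_set(sweep(s$points, 2, -t), labels = s$labels,
                     modality = "CT")
  expect_equal(unname(centroid(s2)), unname(centroid(s)) + t)
})

test_that("marker matching recovers shuffles and breaks ties by label", {
  a <- tri_set("MRI")
  expect_equal(unname(match_markers(a, tri_set())), 1:3)

  # scalene triangle so the correspondence is geometrically unique
  sc <- fiducial_set(rbind(c(0, 0, 0), c(30, 0, 0), c(0, 20, 0)),
                     labels = c("F1", "F2", "F3"), modality = "MRI")
  perm <- c(3L, 1L, 2L)
  b <- fiducial_set(sc$points[perm, ], labels = paste0("G", 1:3),
                    modality = "CT")
  m <- match_markers(sc, b)
  # a marker i must map to the b row holding the same point
  expect_equal(unname(m), order(perm))

  # equilateral triangle rotated by 120 degrees: several zero-cost
  # permutations; tie-break must be deterministic
  eq <- fiducial_set(rbind(c(1, 0, 0), c(-0.5, sqrt(3) / 2, 0),
                           c(-0.5, -sqrt(3) / 2, 0)),
                     labels = c("A", "B", "C"), modality = "CT")
  m1 <- match_markers(eq, eq)
  m2 <- match_markers(eq, eq)
  expect_identical(m1, m2)

  four <- fiducial_set(rbind(a$points, c(15, 15, 10)), modality = "CT")
  expect_error(match_markers(a, four), "cardinality")
})

test_that("worked triangle example matches direct vector arithmetic", {
  mri <- tri_set("MRI")
  ct_pts <- rbind(c(0, 0, 0), c(31.5, 0, 0), c(0, 30, 0))
  ct <- fiducial_set(ct_pts, labels = c("F1", "F2", "F3"), modality = "CT")
  res <- fiducial_qa(mri, ct, tol_mm = 1.0)

  # independent computation, straight from the definition
  c_mri <- colMeans(mri$points)            # (10, 10, 0)
  c_ct <- colMeans(ct_pts)                 # (10.5, 10, 0)
  d_mri <- sqrt(rowSums(sweep(mri$points, 2, c_mri)^2))
  d_ct <- sqrt(rowSums(sweep(ct_pts, 2, c_ct)^2))
  expect_equal(unname(c_ct), c(10.5, 10, 0))
  expect_lt(max(abs(res$per_marker$diff_mm - (d_mri - d_ct))), 1e-9)
  expect_equal(res$per_marker$diff_mm[2], sqrt(500) - sqrt(541),
               tolerance = 1e-9)           # -0.8987 mm
  expect_true(res$passed)

  # marker 2 moved 2 mm radially -> outside the 1 mm tolerance
  ct2 <- fiducial_set(rbind(c(0, 0, 0), c(32, 0, 0), c(0, 30, 0)),
                      labels = ct$labels, modality = "CT")
  res2 <- fiducial_qa(mri, ct2, tol_mm = 1.0)
  expect_gt(res2$max_abs_diff_mm, 1.0)
  expect_false(res2$passed)
})

test_that("distance-to-centroid differences are rigid-invariant", {
  set.seed(99)
  for (rep in 1:25) {
    pts <- matrix(rnorm(9, sd = 15), 3, 3)
    while (min(dist(pts)) < 5) pts <- matrix(rnorm(9, sd = 15), 3, 3)
    s <- fiducial_set(pts, modality = "MRI")
    moved <- apply_rigid(fiducial_set(pts, modality = "CT"), random_rigid())
    res <- fiducial_qa(s, moved)
    expect_lt(res$max_abs_diff_mm, 1e-9)
    expect_true(res$passed)
  }
})

test_that("swapping the inputs negates the differences", {
  set.seed(31)
  a <- fiducial_set(matrix(rnorm(9, sd = 15), 3, 3), modality = "MRI")
  b <- fiducial_set(a$points + matrix(rnorm(9, sd = 0.3), 3, 3),
                    modality = "CT")
  ab <- fiducial_qa(a, b)
  ba <- fiducial_qa(fiducial_set(b$points, modality = "MRI"),
                    fiducial_set(a$points, modality = "CT"))
  expect_equal(sort(ba$per_marker$diff_mm), sort(-ab$per_marker$diff_mm),
               tolerance = 1e-12)
  expect_equal(ab$passed, ba$passed)
})

test_that("uniform scaling of one set is detected in proportion", {
  set.seed(41)
  pts <- matrix(rnorm(9, sd = 20), 3, 3)
  s <- fiducial_set(pts, modality = "MRI")
  d <- sqrt(rowSums(sweep(pts, 2, colMeans(pts))^2))
  for (scale in c(0.02, 0.05)) {
    ctr <- colMeans(pts)
    scaled <- sweep(pts, 2, ctr) * (1 + scale)
    ct <- fiducial_set(sweep(scaled, 2, -ctr), modality = "CT")
    res <- fiducial_qa(s, ct)
    expect_equal(res$per_marker$diff_mm, -scale * d, tolerance = 1e-9)
  }
})
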