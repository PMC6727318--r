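test_that("identical doses give gamma zero everywhere", {
  set.seed(5)
  pr <- smooth_dose_pair(5, n = 16)
  res <- compute_gamma(pr$ref, pr$ref, gamma_criteria(2, 2),
                       all_true_mask(pr$ref))
  expect_equal(res$pass_rate_pct, 100.0)
  expect_lt(res$mean_gamma, 1e-12)
  expect_equal(res$n_evaluated, 16^3)
})

test_that("uniform-field closed form: 2% error at 2%/2mm sits exactly at 1", {
  ref <- uniform_dose(2.0, n = 12)
  ev <- uniform_dose(2.0 * 1.02, n = 12)
  res <- compute_gamma(ref, ev, gamma_criteria(2, 2), all_true_mask(ref))
  g <- res$gamma_map$values
  expect_lt(max(abs(g - 1)), 1e-6)
  expect_equal(res$pass_rate_pct, 100.0)  # gamma <= 1 passes, inclusive

  ev2 <- uniform_dose(2.0 * 1.021, n = 12)
  res2 <- compute_gamma(ref, ev2, gamma_criteria(2, 2), all_true_mask(ref))
  expect_equal(res2$pass_rate_pct, 0.0)
})

test_that("engine equals the exhaustive oracle on random smooth pairs", {
  for (seed in c(101, 202)) {
    pr <- smooth_dose_pair(seed, n = 12)
    mask <- all_true_mask(pr$ref)
    for (cr in list(gamma_criteria(3, 3), gamma_criteria(2, 1))) {
      fast <- compute_gamma(pr$ref, pr$eval, cr, mask)
      slow <- gamma_oracle(pr$ref, pr$eval, cr, mask)
      expect_lt(max(abs(fast$gamma_map$values - slow$gamma_map$values),
                    na.rm = TRUE), 1e-6)
    }
  }
})

test_that("gamma is invariant under global dose rescaling", {
  pr <- smooth_dose_pair(77, n = 12)
  mask <- all_true_mask(pr$ref)
  cr <- gamma_criteria(2, 2)
  base <- compute_gamma(pr$ref, pr$eval, cr, mask)
  for (c_scale in c(0.25, 40)) {
    r2 <- pr$ref; r2$grid$values <- r2$grid$values * c_scale
    e2 <- pr$eval; e2$grid$values <- e2$grid$values * c_scale
    scaled <- compute_gamma(r2, e2, cr, mask)
    expect_lt(max(abs(scaled$gamma_map$values - base$gamma_map$values)),
              1e-9)
  }
})

test_that("criteria nesting orders the pass rates", {
  for (seed in c(8, 9)) {
    pr <- smooth_dose_pair(seed, n = 14)
    # exaggerate the disagreement so rates are not all 100
    pr$eval$grid$values <- pr$eval$grid$values * 1.015
    mask <- all_true_mask(pr$ref)
    p33 <- compute_gamma(pr$ref, pr$eval, gamma_criteria(3, 3), mask)$pass_rate_pct
    p22 <- compute_gamma(pr$ref, pr$eval, gamma_criteria(2, 2), mask)$pass_rate_pct
    p21 <- compute_gamma(pr$ref, pr$eval, gamma_criteria(2, 1), mask)$pass_rate_pct
    expect_gte(p33, p22)
    expect_gte(p22, p21)
  }
})

test_that("a rigid 2 mm shift of a linear gradient passes 2%/2 mm", {
  n <- 15; sp <- 1
  org <- -(n - 1) / 2 * sp
  coords <- org + (seq_len(n) - 1) * sp
  W <- as.matrix(expand.grid(coords, coords, coords))
  mkdose <- function(shift) {
    v <- array(10 + 0.05 * (W[, 1] - shift), c(n, n, n))
    dose_grid(voxel_grid(v, rep(org, 3), rep(sp, 3)), c(0, 0, 0))
  }
  ref <- mkdose(0)
  ev <- mkdose(2)  # pure 2 mm shift along x
  # interior mask so the shifted match stays in-grid
  inner <- array(FALSE, c(n, n, n)); inner[5:11, 5:11, 5:11] <- TRUE
  mask <- binary_mask(inner, rep(org, 3), rep(sp, 3))
  res <- gamma_oracle(ref, ev, gamma_criteria(2, 2, search_step_mm = 0.5),
                      mask)
  expect_true(all(res$gamma_map$values[inner] <= 1 + 1e-9))
  expect_equal(res$pass_rate_pct, 100.0)
})

test_that("local normalization and empty masks behave as documented", {
  pr <- smooth_dose_pair(55, n = 10)
  mask <- all_true_mask(pr$ref)
  loc <- compute_gamma(pr$ref, pr$eval,
                       gamma_criteria(2, 2, normalization = "local"), mask)
  glob <- compute_gamma(pr$ref, pr$eval, gamma_criteria(2, 2), mask)
  # local denominators are <= global max, so local gamma >= global gamma
  expect_true(all(loc$gamma_map$values >= glob$gamma_map$values - 1e-9))

  empty <- binary_mask(array(FALSE, pr$ref$grid$dims), pr$ref$grid$origin,
                       pr$ref$grid$spacing)
  expect_warning(r0 <- compute_gamma(pr$ref, pr$eval, gamma_criteria(2, 2),
                                     empty), "empty")
  expect_equal(r0$n_evaluated, 0L)
  expect_true(is.na(r0$pass_rate_pct))

  zero <- uniform_dose(0.0, n = 6)
  zero$grid$values[] <- 0
  expect_error(compute_gamma(zero, zero, gamma_criteria(2, 2),
                             all_true_mask(zero)), "zero")
})

test_that("edge-limited voxels are flagged, not dropped", {
  # a uniform 3% error keeps the search alive (gamma 1.5 everywhere), so
  # border voxels must consult out-of-grid candidates and get flagged
  ref <- uniform_dose(2, n = 8, spacing = 1)
  ev <- uniform_dose(2 * 1.03, n = 8, spacing = 1)
  res <- compute_gamma(ref, ev, gamma_criteria(2, 2), all_true_mask(ref))
  expect_equal(res$n_evaluated, 8^3)
  expect_gt(res$n_edge_limited, 0)
  expect_equal(res$pass_rate_pct, 0.0)
  expect_equal(max(abs(res$gamma_map$values - 1.5)), 0, tolerance = 1e-9)
})

test_that("isocenter dose check arithmetic and boundary", {
  mk <- function(val) uniform_dose(val, n = 8)
  expect_equal(isocenter_dose_check(mk(2.00), mk(2.00))$diff_pct, 0.0)
  chk <- isocenter_dose_check(mk(2.00), mk(2.04))
  expect_equal(chk$diff_pct, 2.0)
  expect_true(chk$passed)     # boundary inclusive
  chk2 <- isocenter_dose_check(mk(2.00), mk(2.05))
  expect_equal(chk2$diff_pct, 2.5)
  expect_false(chk2$passed)
  expect_error(isocenter_dose_check(mk(0), mk(1)), "not positive|non-negative")
})
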