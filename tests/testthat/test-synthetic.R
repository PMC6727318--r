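test_that("phantom body volume matches the analytic elliptic cylinder", {
  spec <- phantom_spec()  # stated defaults: 180 x 120 mm, length 200
  ph <- make_phantom(spec)
  vvox <- prod(spec$spacing_mm)
  analytic <- pi * 180 * 120 * 200
  measured <- sum(ph$masks$body$values) * vvox
  expect_lt(abs(measured - analytic) / analytic, 0.02)
  expect_equal(ph$isocenter, c(0, 0, 0))
})

test_that("phantom generation is deterministic and fiducials well-spread", {
  a <- make_phantom(small_phantom_spec())
  b <- make_phantom(small_phantom_spec())
  expect_identical(a$ct$values, b$ct$values)
  d <- dist(a$fiducials_ct$points)
  expect_true(all(d >= 5))
})

test_that("pseudo-CT perturbations are exactly as specified", {
  ph <- make_phantom(small_phantom_spec())
  ident <- make_pseudo_ct(ph$ct, ph$masks, perturbation_spec())
  expect_identical(ident$values, ph$ct$values)

  p40 <- make_pseudo_ct(ph$ct, ph$masks, perturbation_spec(tissue_hu_bias = 40))
  soft <- ph$masks$body$values & !ph$masks$bone$values
  diff <- p40$values - ph$ct$values
  expect_true(all(diff[soft] == 40))
  expect_true(all(diff[!soft] == 0))

  pb <- make_pseudo_ct(ph$ct, ph$masks, perturbation_spec(bone_hu_bias = -100))
  diffb <- pb$values - ph$ct$values
  expect_true(all(diffb[ph$masks$bone$values] == -100))
  expect_true(all(diffb[!ph$masks$bone$values] == 0))
})

test_that("skin layer dilation grows each slice by about perimeter x t", {
  # 1 mm pixels so a 1 mm shell is one-pixel dilation
  spec <- phantom_spec(body_semiaxes_mm = c(60, 40), body_length_mm = 20,
                       spacing_mm = c(1, 1, 5), femhead_offset_mm = 35,
                       femhead_radius_mm = 8, ring_outer_mm = c(35, 25),
                       ring_inner_mm = c(28, 18), ring_length_mm = 12,
                       prostate_radius_mm = 8, air_margin_mm = 5)
  ph <- make_phantom(spec)
  pct <- make_pseudo_ct(ph$ct, ph$masks, perturbation_spec(skin_layer_mm = 1))
  k <- which.max(apply(ph$masks$body$values, 3, sum))  # a full body slice
  before <- sum(ph$ct$values[, , k] > -300)
  after <- sum(pct$values[, , k] > -300)
  # Ramanujan perimeter of the 60 x 40 ellipse
  a <- 60; b <- 40
  h <- ((a - b) / (a + b))^2
  perim <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  expect_lt(abs((after - before) - perim) / perim, 0.25)
  expect_gt(after, before)
})

test_that("toy dose engine reduces to exponential attenuation in water", {
  water <- water_cylinder(radius = 70, length_mm = 60, spacing = 2)
  beams <- beam_spec(n_beams = 1, half_width_mm = 25, z_half_mm = 25,
                     prescription_gy = 2)
  # dose sampled along the beam axis (single beam travels along +y)
  ys <- seq(-60, 60, by = 2)
  geom <- voxel_grid(array(0, c(3, length(ys), 3)),
                     origin = c(-2, -60, -2), spacing = c(2, 2, 2))
  d <- toy_dose_engine(water, beams, c(0, 0, 0), dose_grid_geom = geom)
  axis_dose <- d$grid$values[2, , 2]
  depth <- ys + 70  # surface at y = -70
  sel <- depth >= 20 & depth <= 120  # interior, away from the surface ramp
  fit <- stats::lm(log(axis_dose[sel]) ~ depth[sel])
  expect_lt(abs(-coef(fit)[2] - beams$mu_per_mm) / beams$mu_per_mm, 0.01)
})

test_that("a denser slab attenuates downstream dose by exp(-mu t)", {
  water <- water_cylinder(radius = 70, length_mm = 60, spacing = 2)
  slab <- water
  # rho 2 in a 20 mm-thick slab across the beam: extra WEPL = 20 mm
  yc <- slab$origin[2] + (seq_len(slab$dims[2]) - 1) * 2
  idx <- which(yc >= -40 & yc < -20)
  slab$values[, idx, ][slab$values[, idx, ] > -300] <- 1000  # rho = 2
  beams <- beam_spec(n_beams = 1, half_width_mm = 25, z_half_mm = 25)
  geom <- voxel_grid(array(0, c(1, 1, 1)), origin = c(0, 30, 0),
                     spacing = c(2, 2, 2))
  raw_dose <- function(img) {
    # bypass prescription scaling: compare unscaled engine output
    planqa:::cpp_raytrace_dose(as.numeric(img$values), as.integer(img$dims),
                               img$origin, img$spacing,
                               as.integer(geom$dims), geom$origin,
                               geom$spacing, c(0, 0, 0), 0, 0.005,
                               25, 25, 3, min(img$spacing) / 2)[1]
  }
  ratio <- raw_dose(slab) / raw_dose(water)
  expect_equal(ratio, exp(-0.005 * 20), tolerance = 0.02)
})

test_that("an all-water CT and a zero-HU CT give identical doses", {
  water <- water_cylinder(radius = 50, length_mm = 40, spacing = 2.5)
  zero <- water
  zero$values[] <- 0  # rho = 1 everywhere, including the former air
  b <- beam_spec(n_beams = 3, half_width_mm = 20, z_half_mm = 15)
  # identical interiors only matter where rays stay in tissue; compare the
  # maps where the water phantom is tissue on the straight-through path
  d1 <- toy_dose_engine(water, b, c(0, 0, 0))
  d2 <- toy_dose_engine(zero, b, c(0, 0, 0))
  # at HU 0 the density map is the identity: rays through the all-zero CT
  # accumulate extra WEPL only outside the cylinder; inside, after
  # isocenter normalization the two differ only by that constant factor
  ctr <- sample_trilinear(d1$grid, c(0, 10, 0)) /
         sample_trilinear(d2$grid, c(0, 10, 0))
  expect_equal(ctr, 1, tolerance = 0.05)
})

test_that("isocenter dose decreases as tissue HU bias increases", {
  ph <- make_phantom(small_phantom_spec())
  beams <- small_beams()
  iso_dose_raw <- function(bias) {
    pct <- make_pseudo_ct(ph$ct, ph$masks,
                          perturbation_spec(tissue_hu_bias = bias))
    geom <- voxel_grid(array(0, c(5, 5, 3)), origin = c(-8, -8, -4),
                       spacing = c(4, 4, 4))
    b2 <- beams; b2$prescription_gy <- 1  # scale away; use raw sum
    planqa:::cpp_raytrace_dose(as.numeric(pct$values), as.integer(pct$dims),
                               pct$origin, pct$spacing, as.integer(geom$dims),
                               geom$origin, geom$spacing, c(0, 0, 0),
                               2 * pi * (0:6) / 7, beams$mu_per_mm,
                               beams$half_width_mm, beams$z_half_mm,
                               beams$penumbra_mm, min(pct$spacing) / 2)[38]
  }
  doses <- vapply(c(0, 40, 80, 160), iso_dose_raw, numeric(1))
  expect_true(all(diff(doses) < 0))
})

test_that("fixed-MU semantics: HU bias shifts the isocenter dose check", {
  # identity case: recalculation on the identical CT gives a zero diff
  ident <- make_case(small_phantom_spec(), perturbation_spec(), small_beams())
  chk0 <- isocenter_dose_check(ident$ref_dose, ident$eval_dose)
  expect_equal(chk0$diff_pct, 0, tolerance = 1e-9)

  # denser pseudo-CT soft tissue: plan normalized on pseudo-CT, so the
  # QA-CT recalculation (same MUs, less attenuation) reads higher ->
  # negative eval-vs-ref difference
  biased <- make_case(small_phantom_spec(),
                      perturbation_spec(tissue_hu_bias = 160), small_beams())
  chk <- isocenter_dose_check(biased$ref_dose, biased$eval_dose)
  expect_lt(chk$diff_pct, 0)
})
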