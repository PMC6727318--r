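# Shared fixture builders. Everything is generated in code at test time;
# phantoms used outside the acceptance tests are scaled down (coarser
# spacing, smaller anatomy) to keep the default run fast.

# uniform-dose cube: n^3 voxels, `spacing` mm pitch, centered on 0
uniform_dose <- function(value, n = 20, spacing = 1.5) {
  org <- -(n - 1) / 2 * spacing
  g <- voxel_grid(array(value, c(n, n, n)), origin = rep(org, 3),
                  spacing = rep(spacing, 3))
  dose_grid(g, c(0, 0, 0))
}

all_true_mask <- function(dose) {
  binary_mask(array(TRUE, dose$grid$dims), origin = dose$grid$origin,
              spacing = dose$grid$spacing)
}

# smooth random dose: sum of Gaussian blobs, strictly positive
smooth_random_dose <- function(n = 30, spacing = 1.5, n_blobs = 5,
                               base = 0.2) {
  org <- -(n - 1) / 2 * spacing
  ax <- org + (seq_len(n) - 1) * spacing
  X <- array(rep(ax, times = n * n), c(n, n, n))
  Y <- array(rep(rep(ax, each = n), times = n), c(n, n, n))
  Z <- array(rep(ax, each = n * n), c(n, n, n))
  v <- array(base, c(n, n, n))
  ext <- (n - 1) * spacing / 2
  for (b in seq_len(n_blobs)) {
    ctr <- runif(3, -ext / 2, ext / 2)
    w <- runif(1, 8, 18)
    amp <- runif(1, 0.5, 2)
    v <- v + amp * exp(-((X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2) /
                         (2 * w^2))
  }
  dose_grid(voxel_grid(v, origin = rep(org, 3), spacing = rep(spacing, 3)),
            c(0, 0, 0))
}

# paired ref/eval smooth doses differing by a small smooth perturbation
smooth_dose_pair <- function(seed, n = 30, spacing = 1.5) {
  set.seed(seed)
  ref <- smooth_random_dose(n, spacing)
  pert <- smooth_random_dose(n, spacing, n_blobs = 3, base = 0)
  ev <- ref
  ev$grid$values <- ref$grid$values * (1 + 0.03 * (pert$grid$values /
                                                     max(pert$grid$values) - 0.5))
  list(ref = ref, eval = ev)
}

# random rigid transform (uniform random rotation via QR, plus translation)
random_rigid <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(R = q, t = rnorm(3, sd = 30))
}

apply_rigid <- function(set, rt) {
  fiducial_set(t(rt$R %*% t(set$points)) +
                 matrix(rt$t, nrow(set$points), 3, byrow = TRUE),
               labels = set$labels, modality = set$modality)
}

# small, fast phantom for pipeline tests (not the stated defaults)
small_phantom_spec <- function(spacing = 4) {
  phantom_spec(body_semiaxes_mm = c(80, 60), body_length_mm = 80,
               spacing_mm = spacing, femhead_radius_mm = 12,
               femhead_offset_mm = 55, ring_outer_mm = c(50, 36),
               ring_inner_mm = c(40, 26), ring_length_mm = 50,
               prostate_radius_mm = 12, air_margin_mm = 8)
}

small_beams <- function(...) {
  beam_spec(half_width_mm = 20, z_half_mm = 20, ...)
}

# uniform water cylinder in air (for attenuation tests)
water_cylinder <- function(radius = 70, length_mm = 60, spacing = 2) {
  half <- c(radius + 10, radius + 10, length_mm / 2 + 10)
  dims <- as.integer(2 * ceiling(half / spacing) + 1)
  org <- -(dims - 1) / 2 * spacing
  ax <- lapply(1:3, function(a) org[a] + (seq_len(dims[a]) - 1) * spacing)
  X <- array(rep(ax[[1]], times = dims[2] * dims[3]), dims)
  Y <- array(rep(rep(ax[[2]], each = dims[1]), times = dims[3]), dims)
  Z <- array(rep(ax[[3]], each = dims[1] * dims[2]), dims)
  hu <- array(-1000, dims)
  hu[X^2 + Y^2 <= radius^2 & abs(Z) <= length_mm / 2] <- 0
  voxel_grid(hu, origin = org, spacing = rep(spacing, 3))
}
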