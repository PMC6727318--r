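#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Toy broad-beam dose engine: per beam, primary fluence attenuated
// exponentially with water-equivalent path length (WEPL), modulated by a
// smooth (erfc) lateral/longitudinal aperture profile. No scatter, no
// buildup — deliberately simple, direction-correct only.

static inline bool tri3(const double *v, int nx, int ny, int nz,
                        double ix, double iy, double iz, double &out) {
  if (ix < 0.0 || iy < 0.0 || iz < 0.0 ||
      ix > nx - 1.0 || iy > ny - 1.0 || iz > nz - 1.0)
    return false;
  int i0 = (int)std::floor(ix), j0 = (int)std::floor(iy), k0 = (int)std::floor(iz);
  if (i0 > nx - 2) i0 = nx - 2; if (i0 < 0) i0 = 0;
  if (j0 > ny - 2) j0 = ny - 2; if (j0 < 0) j0 = 0;
  if (k0 > nz - 2) k0 = nz - 2; if (k0 < 0) k0 = 0;
  if (nx == 1) { i0 = 0; ix = 0.0; }
  if (ny == 1) { j0 = 0; iy = 0.0; }
  if (nz == 1) { k0 = 0; iz = 0.0; }
  double fx = ix - i0, fy = iy - j0, fz = iz - k0;
  int i1 = (nx == 1) ? i0 : i0 + 1, j1 = (ny == 1) ? j0 : j0 + 1,
      k1 = (nz == 1) ? k0 : k0 + 1;
  const size_t sy = (size_t)nx, sz = (size_t)nx * ny;
  #define V(a,b,c) v[(a) + (b)*sy + (c)*sz]
  double c00 = V(i0,j0,k0)*(1-fx) + V(i1,j0,k0)*fx;
  double c10 = V(i0,j1,k0)*(1-fx) + V(i1,j1,k0)*fx;
  double c01 = V(i0,j0,k1)*(1-fx) + V(i1,j0,k1)*fx;
  double c11 = V(i0,j1,k1)*(1-fx) + V(i1,j1,k1)*fx;
  #undef V
  out = (c00*(1-fy) + c10*fy)*(1-fz) + (c01*(1-fy) + c11*fy)*fz;
  return true;
}

// relative electron density from HU, clipped to [0, 2]
static inline double hu_to_density(double hu) {
  double rho = 1.0 + hu / 1000.0;
  if (rho < 0.0) rho = 0.0;
  if (rho > 2.0) rho = 2.0;
  return rho;
}

// [[Rcpp::export]]
NumericVector cpp_raytrace_dose(NumericVector huv, IntegerVector ct_dims,
                                NumericVector ct_origin, NumericVector ct_spacing,
                                IntegerVector dose_dims, NumericVector dose_origin,
                                NumericVector dose_spacing, NumericVector iso,
                                NumericVector angles_rad, double mu_per_mm,
                                double half_width_mm, double z_half_mm,
                                double penumbra_mm, double step_mm) {
  int cx = ct_dims[0], cy = ct_dims[1], cz = ct_dims[2];
  int nx = dose_dims[0], ny = dose_dims[1], nz = dose_dims[2];
  size_t ntot = (size_t)nx * ny * nz;
  const double *hu = huv.begin();
  NumericVector dose(ntot, 0.0);
  const double SQRT2 = std::sqrt(2.0);
  // extent of the CT volume along any axis, used to bound the ray march
  double diag = 0.0;
  for (int a = 0; a < 3; ++a) {
    double ext = (ct_dims[a] - 1) * ct_spacing[a];
    diag += ext * ext;
  }
  diag = std::sqrt(diag);
  int nsteps = (int)std::ceil(diag / step_mm);

  for (R_xlen_t b = 0; b < angles_rad.size(); ++b) {
    double th = angles_rad[b];
    // beam travel direction in the axial plane; gantry rotates about z
    double ux = std::sin(th), uy = std::cos(th);
    for (size_t s = 0; s < ntot; ++s) {
      int i = s % nx, j = (s / nx) % ny;
      int k = s / ((size_t)nx * ny);
      double px = dose_origin[0] + i * dose_spacing[0];
      double py = dose_origin[1] + j * dose_spacing[1];
      double pz = dose_origin[2] + k * dose_spacing[2];
      // aperture profile
      double vx = px - iso[0], vy = py - iso[1], vz = pz - iso[2];
      double lat = std::fabs(vx * uy - vy * ux);  // in-plane distance to axis
      double prof = 0.25 * std::erfc((lat - half_width_mm) / (SQRT2 * penumbra_mm))
                         * std::erfc((std::fabs(vz) - z_half_mm) / (SQRT2 * penumbra_mm));
      if (prof < 1e-8) continue;
      // WEPL: march back toward the source, midpoint rule
      double wepl = 0.0;
      for (int t = 0; t < nsteps; ++t) {
        double tt = (t + 0.5) * step_mm;
        double qx = px - tt * ux, qy = py - tt * uy;
        double ci = (qx - ct_origin[0]) / ct_spacing[0];
        double cj = (qy - ct_origin[1]) / ct_spacing[1];
        double ck = (pz - ct_origin[2]) / ct_spacing[2];
        double h;
        if (!tri3(hu, cx, cy, cz, ci, cj, ck, h)) {
          if (tt > step_mm) break;  // left the volume: upstream is air
          continue;
        }
        wepl += hu_to_density(h) * step_mm;
      }
      dose[s] += prof * std::exp(-mu_per_mm * wepl);
    }
  }
  return dose;
}
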