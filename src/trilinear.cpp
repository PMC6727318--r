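#include <Rcpp.h>
using namespace Rcpp;

// Trilinear interpolation at a continuous 0-based voxel index.
// Arrays are R column-major: (i,j,k) -> i + nx*(j + ny*k).
// Returns false when the index lies outside [0, n-1] on any axis.
static inline bool tri_sample(const double *v, int nx, int ny, int nz,
                              double ix, double iy, double iz, double &out) {
  if (ix < 0.0 || iy < 0.0 || iz < 0.0 ||
      ix > nx - 1.0 || iy > ny - 1.0 || iz > nz - 1.0)
    return false;
  int i0 = (int)std::floor(ix), j0 = (int)std::floor(iy), k0 = (int)std::floor(iz);
  if (i0 > nx - 2) i0 = nx - 2; if (i0 < 0) i0 = 0;
  if (j0 > ny - 2) j0 = ny - 2; if (j0 < 0) j0 = 0;
  if (k0 > nz - 2) k0 = nz - 2; if (k0 < 0) k0 = 0;
  // degenerate single-voxel axes
  if (nx == 1) { i0 = 0; ix = 0.0; }
  if (ny == 1) { j0 = 0; iy = 0.0; }
  if (nz == 1) { k0 = 0; iz = 0.0; }
  double fx = ix - i0, fy = iy - j0, fz = iz - k0;
  int i1 = (nx == 1) ? i0 : i0 + 1;
  int j1 = (ny == 1) ? j0 : j0 + 1;
  int k1 = (nz == 1) ? k0 : k0 + 1;
  const size_t sx = 1, sy = (size_t)nx, sz = (size_t)nx * ny;
  #define V(a,b,c) v[(a)*sx + (b)*sy + (c)*sz]
  double c00 = V(i0,j0,k0) * (1 - fx) + V(i1,j0,k0) * fx;
  double c10 = V(i0,j1,k0) * (1 - fx) + V(i1,j1,k0) * fx;
  double c01 = V(i0,j0,k1) * (1 - fx) + V(i1,j0,k1) * fx;
  double c11 = V(i0,j1,k1) * (1 - fx) + V(i1,j1,k1) * fx;
  #undef V
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  out = c0 * (1 - fz) + c1 * fz;
  return true;
}

// [[Rcpp::export]]
NumericVector cpp_sample_trilinear(NumericVector values, IntegerVector dims,
                                   NumericVector origin, NumericVector spacing,
                                   NumericMatrix pts, bool halfvoxel) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = pts.nrow();
  NumericVector out(n);
  const double *v = values.begin();
  for (int r = 0; r < n; ++r) {
    double idx[3];
    bool inside = true;
    for (int a = 0; a < 3; ++a) {
      double ci = (pts(r, a) - origin[a]) / spacing[a];
      double hi = dims[a] - 1.0;
      if (halfvoxel) {
        if (ci < -0.5 - 1e-9 || ci > hi + 0.5 + 1e-9) { inside = false; break; }
        if (ci < 0.0) ci = 0.0;
        if (ci > hi) ci = hi;
      }
      idx[a] = ci;
    }
    double val = NA_REAL;
    if (inside && !tri_sample(v, nx, ny, nz, idx[0], idx[1], idx[2], val))
      val = NA_REAL;
    out[r] = inside ? val : NA_REAL;
  }
  return out;
}
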