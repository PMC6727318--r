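#include <Rcpp.h>
#include <vector>
#include <queue>
#include <limits>
using namespace Rcpp;

// ---- 3D largest connected component, 26-connectivity -----------------

// [[Rcpp::export]]
LogicalVector cpp_largest_cc(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t ntot = (size_t)nx * ny * nz;
  std::vector<int> label(ntot, 0);
  int nlab = 0;
  std::vector<size_t> sizes(1, 0);
  std::vector<size_t> stack;
  for (size_t s = 0; s < ntot; ++s) {
    if (!mask[s] || label[s]) continue;
    ++nlab;
    sizes.push_back(0);
    stack.clear();
    stack.push_back(s);
    label[s] = nlab;
    while (!stack.empty()) {
      size_t cur = stack.back();
      stack.pop_back();
      ++sizes[nlab];
      int i = cur % nx, j = (cur / nx) % ny, k = cur / ((size_t)nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            size_t nb = ii + (size_t)nx * (jj + (size_t)ny * kk);
            if (mask[nb] && !label[nb]) {
              label[nb] = nlab;
              stack.push_back(nb);
            }
          }
    }
  }
  LogicalVector out(ntot, false);
  if (nlab == 0) return out;
  int best = 1;
  for (int l = 2; l <= nlab; ++l)
    if (sizes[l] > sizes[best]) best = l;
  for (size_t s = 0; s < ntot; ++s) out[s] = (label[s] == best);
  return out;
}

// ---- per-slice hole filling (background flood from slice border) -----

// [[Rcpp::export]]
LogicalVector cpp_fill_holes_2d(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out(clone(mask));
  std::vector<char> outside((size_t)nx * ny);
  std::vector<int> stack;
  for (int k = 0; k < nz; ++k) {
    size_t off = (size_t)nx * ny * k;
    std::fill(outside.begin(), outside.end(), 0);
    stack.clear();
    for (int i = 0; i < nx; ++i) {
      for (int jb : {0, ny - 1}) {
        size_t p = i + (size_t)nx * jb;
        if (!mask[off + p] && !outside[p]) { outside[p] = 1; stack.push_back(p); }
      }
    }
    for (int j = 0; j < ny; ++j) {
      for (int ib : {0, nx - 1}) {
        size_t p = ib + (size_t)nx * j;
        if (!mask[off + p] && !outside[p]) { outside[p] = 1; stack.push_back(p); }
      }
    }
    while (!stack.empty()) {
      int p = stack.back();
      stack.pop_back();
      int i = p % nx, j = p / nx;
      const int di[4] = {1, -1, 0, 0}, dj[4] = {0, 0, 1, -1};
      for (int t = 0; t < 4; ++t) {
        int ii = i + di[t], jj = j + dj[t];
        if (ii < 0 || jj < 0 || ii >= nx || jj >= ny) continue;
        int q = ii + nx * jj;
        if (!mask[off + q] && !outside[q]) { outside[q] = 1; stack.push_back(q); }
      }
    }
    for (size_t p = 0; p < (size_t)nx * ny; ++p)
      if (!mask[off + p] && !outside[p]) out[off + p] = true;
  }
  return out;
}

// ---- exact squared Euclidean distance transform (Felzenszwalb) -------

static void dt1d(std::vector<double> &f, std::vector<double> &d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double ZINF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -ZINF;
  z[1] = ZINF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = ZINF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Squared distance (in pixels) from every pixel to the nearest pixel of
// `from` (per axial slice). INF where a slice has no `from` pixel.
static void edt2_slices(const LogicalVector &mask, int nx, int ny, int nz,
                        bool from_true, std::vector<double> &sq) {
  // large finite sentinel: infinity breaks the parabola intersection
  const double INF = 1e18;
  sq.assign((size_t)nx * ny * nz, INF);
  std::vector<double> f(std::max(nx, ny)), d(std::max(nx, ny));
  for (int k = 0; k < nz; ++k) {
    size_t off = (size_t)nx * ny * k;
    // columns first
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j)
        f[j] = (mask[off + i + (size_t)nx * j] == from_true) ? 0.0 : INF;
      dt1d(f, d, ny);
      for (int j = 0; j < ny; ++j) sq[off + i + (size_t)nx * j] = d[j];
    }
    // then rows
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) f[i] = sq[off + i + (size_t)nx * j];
      dt1d(f, d, nx);
      for (int i = 0; i < nx; ++i) sq[off + i + (size_t)nx * j] = d[i];
    }
  }
}

// Erosion by a discrete disk of radius r_vox (pixels): a foreground pixel
// survives iff no background pixel lies within Euclidean distance r_vox.
// [[Rcpp::export]]
LogicalVector cpp_erode2d(LogicalVector mask, IntegerVector dims, double r_vox) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> sq;
  edt2_slices(mask, nx, ny, nz, false, sq);
  size_t ntot = (size_t)nx * ny * nz;
  LogicalVector out(ntot, false);
  double r2 = r_vox * r_vox;
  for (size_t s = 0; s < ntot; ++s)
    out[s] = mask[s] && sq[s] > r2;
  return out;
}

// Dilation by the same disk: background pixel joins iff a foreground pixel
// lies within distance r_vox.
// [[Rcpp::export]]
LogicalVector cpp_dilate2d(LogicalVector mask, IntegerVector dims, double r_vox) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> sq;
  edt2_slices(mask, nx, ny, nz, true, sq);
  size_t ntot = (size_t)nx * ny * nz;
  LogicalVector out(ntot, false);
  double r2 = r_vox * r_vox;
  for (size_t s = 0; s < ntot; ++s)
    out[s] = mask[s] || sq[s] <= r2;
  return out;
}
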