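#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Binary dilation with an arbitrary voxel-offset structuring element.
// offsets: n x 3 integer voxel offsets (0-based axis order x,y,z).
// [[Rcpp::export]]
LogicalVector cpp_dilate(const LogicalVector& mask, const IntegerVector& dims,
                         const IntegerMatrix& offsets) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out((R_xlen_t)nx * ny * nz);
  const int no = offsets.nrow();
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        const R_xlen_t idx = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        if (!mask[idx]) continue;
        for (int k = 0; k < no; ++k) {
          const int xx = x + offsets(k, 0);
          const int yy = y + offsets(k, 1);
          const int zz = z + offsets(k, 2);
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
            continue;
          out[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)] = true;
        }
      }
    }
  }
  return out;
}

static const double DT_INF = 1e20;

// 1-D squared distance transform (Felzenszwalb & Huttenlocher), sample
// spacing^2 = w2.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double w2) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * (double)v[k] * v[k])) /
               (2.0 * w2 * (q - v[k]));
    while (s <= z[k]) {
      --k;
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * (double)v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = w2 * (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Euclidean distance (mm) from every voxel to the nearest set voxel of mask.
// Voxels inside the mask get 0; if the mask is empty, all distances are huge.
// [[Rcpp::export]]
NumericVector cpp_distance_mm(const LogicalVector& mask, const IntegerVector& dims,
                              const NumericVector& spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? 0.0 : DT_INF;

  // pass along x
  {
    std::vector<double> f(nx), d(nx);
    const double w2 = spacing[0] * spacing[0];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        const R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        for (int x = 0; x < nx; ++x) f[x] = g[base + x];
        dt1d(f, d, nx, w2);
        for (int x = 0; x < nx; ++x) g[base + x] = d[x];
      }
  }
  // pass along y
  {
    std::vector<double> f(ny), d(ny);
    const double w2 = spacing[1] * spacing[1];
    for (int z = 0; z < nz; ++z)
      for (int x = 0; x < nx; ++x) {
        for (int y = 0; y < ny; ++y)
          f[y] = g[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
        dt1d(f, d, ny, w2);
        for (int y = 0; y < ny; ++y)
          g[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = d[y];
      }
  }
  // pass along z
  {
    std::vector<double> f(nz), d(nz);
    const double w2 = spacing[2] * spacing[2];
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        for (int z = 0; z < nz; ++z)
          f[z] = g[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
        dt1d(f, d, nz, w2);
        for (int z = 0; z < nz; ++z)
          g[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = d[z];
      }
  }
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(g[i]);
  return out;
}
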