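#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double trilinear(const double* v, const int* dims, double gx,
                               double gy, double gz, bool& inside) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if (gx < 0 || gy < 0 || gz < 0 || gx > nx - 1 || gy > ny - 1 || gz > nz - 1) {
    inside = false;
    return 0.0;
  }
  inside = true;
  int jx = (int)std::floor(gx), jy = (int)std::floor(gy), jz = (int)std::floor(gz);
  if (jx == nx - 1) --jx;
  if (jy == ny - 1) --jy;
  if (jz == nz - 1) --jz;
  if (nx == 1) jx = 0;
  if (ny == 1) jy = 0;
  if (nz == 1) jz = 0;
  const double fx = gx - jx, fy = gy - jy, fz = gz - jz;
  double acc = 0.0;
  for (int a = 0; a <= 1 && jx + a < nx; ++a) {
    const double wa = a ? fx : 1.0 - fx;
    if (wa == 0.0) continue;
    for (int b = 0; b <= 1 && jy + b < ny; ++b) {
      const double wb = b ? fy : 1.0 - fy;
      if (wb == 0.0) continue;
      for (int c = 0; c <= 1 && jz + c < nz; ++c) {
        const double wc = c ? fz : 1.0 - fz;
        if (wc == 0.0) continue;
        acc += wa * wb * wc *
               v[(jx + a) + (R_xlen_t)nx * ((jy + b) + (R_xlen_t)ny * (jz + c))];
      }
    }
  }
  return acc;
}

// Gamma index per reference voxel. Both grids share geometry. Candidate
// displacement offsets (mm, sorted by increasing |r|) are supplied along
// with their precomputed (|r|/DTA)^2 terms; the search breaks off once the
// spatial term alone exceeds the best gamma^2 so far (exact minimum over
// the candidate set). Voxels below the cutoff get NA.
// [[Rcpp::export]]
NumericVector cpp_gamma(const NumericVector& ref, const NumericVector& ev,
                        const IntegerVector& dims, const NumericVector& spacing,
                        double dd_abs, double cutoff_abs,
                        const NumericMatrix& offs,
                        const NumericVector& off_r2_norm) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n, NA_REAL);
  const int no = offs.nrow();
  const double* evp = ev.begin();
  int d[3] = {nx, ny, nz};
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        const R_xlen_t idx = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        const double rd = ref[idx];
        if (rd < cutoff_abs) continue;
        double best = R_PosInf;
        for (int k = 0; k < no; ++k) {
          const double r2 = off_r2_norm[k];
          if (r2 >= best) break;  // offsets sorted: no better candidate left
          const double gx = x + offs(k, 0) / spacing[0];
          const double gy = y + offs(k, 1) / spacing[1];
          const double gz = z + offs(k, 2) / spacing[2];
          bool inside;
          const double e = trilinear(evp, d, gx, gy, gz, inside);
          if (!inside) continue;
          const double dd = (e - rd) / dd_abs;
          const double g2 = dd * dd + r2;
          if (g2 < best) best = g2;
        }
        out[idx] = std::sqrt(best);
      }
    }
  }
  return out;
}
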