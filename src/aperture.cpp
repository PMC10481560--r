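#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// 1-D composite kernel: penumbra blur (discrete Gaussian over fluence bins)
// convolved with the bilinear interpolation hat, evaluated at a continuous
// BEV offset t (mm) from a fluence bin centre.
static inline double kern1d(double t, const std::vector<double>& k, int r,
                            double pitch) {
  double acc = 0.0;
  for (int m = -r; m <= r; ++m) {
    const double x = std::fabs(t - m * pitch) / pitch;
    if (x < 1.0) acc += k[m + r] * (1.0 - x);
  }
  return acc;
}

// penalty of one voxel given its dose, summed over the objectives it
// belongs to (bitmask); kinds: 0 min_dose, 1 max_dose, 2 uniform,
// 3 dose_falloff (per-voxel target in fall_t column fall_col[k])
static inline double vox_penalty(double d, int mask,
                                 const IntegerVector& kind,
                                 const NumericVector& wgt,
                                 const NumericVector& level,
                                 const IntegerVector& fall_col,
                                 const NumericMatrix& fall_t, R_xlen_t vox) {
  double f = 0.0;
  const int K = kind.size();
  for (int k = 0; k < K; ++k) {
    if (!(mask & (1 << k))) continue;
    double r = 0.0;
    switch (kind[k]) {
      case 0: r = d < level[k] ? d - level[k] : 0.0; break;
      case 1: r = d > level[k] ? d - level[k] : 0.0; break;
      case 2: r = d - level[k]; break;
      case 3: {
        const double tgt = fall_t(vox, fall_col[k]);
        r = d > tgt ? d - tgt : 0.0;
        break;
      }
    }
    f += wgt[k] * r * r;
  }
  return f;
}

// One greedy sweep of single-bin leaf-edge moves over all control points
// and leaf pairs. Each proposal's objective change is evaluated exactly on
// the voxels inside the moved bin's kernel support; improving moves are
// applied immediately (dose updated incrementally). `il`/`ir` are 1-based
// open-interval bin indices per (leaf pair, control point), 0 = closed.
// [[Rcpp::export]]
List cpp_refine_sweep(IntegerMatrix il, IntegerMatrix ir,
                      const NumericVector& mu, NumericVector dose,
                      const NumericMatrix& T, const NumericMatrix& U,
                      const NumericMatrix& V, const IntegerMatrix& ordU,
                      const NumericVector& u_centers,
                      const NumericVector& v_centers, double pitch,
                      double sigma, double out_scale,
                      const IntegerVector& memb_mask,
                      const IntegerVector& obj_kind,
                      const NumericVector& obj_w,
                      const NumericVector& obj_level,
                      const IntegerVector& fall_col,
                      const NumericMatrix& fall_t, int max_steps) {
  const int nv = il.nrow(), ncp = il.ncol();
  const int nu = u_centers.size();
  const R_xlen_t n = dose.size();
  const int r = (int)std::ceil(3.0 * sigma / pitch);
  std::vector<double> kk(2 * r + 1);
  double ks = 0.0;
  for (int m = -r; m <= r; ++m) {
    kk[m + r] = std::exp(-0.5 * (m * pitch) * (m * pitch) / (sigma * sigma));
    ks += kk[m + r];
  }
  for (auto& x : kk) x /= ks;
  const double supp = (r + 1) * pitch;

  int n_acc = 0;
  double df_total = 0.0;
  std::vector<R_xlen_t> idxbuf;
  idxbuf.reserve(65536);

  for (int c = 0; c < ncp; ++c) {
    const double muc = mu[c];
    if (muc <= 0.0) continue;
    for (int j = 0; j < nv; ++j) {
      if (il(j, c) == 0) continue;
      // sides: 0 = left edge, 1 = right edge; dirs: grow (+1) / shrink (-1)
      for (int side = 0; side <= 1; ++side) {
        for (int dir = 1; dir >= -1; dir -= 2) {
          for (int stepk = 0; stepk < max_steps; ++stepk) {
            int bin;      // the bin whose fluence toggles
            double delta; // fluence change in that bin
            if (side == 0) {
              bin = dir > 0 ? il(j, c) - 1 : il(j, c);
              delta = dir > 0 ? muc : -muc;
            } else {
              bin = dir > 0 ? ir(j, c) + 1 : ir(j, c);
              delta = dir > 0 ? muc : -muc;
            }
            if (bin < 1 || bin > nu) break;
            if (dir < 0 && il(j, c) >= ir(j, c)) break; // keep one bin open
            const double ub = u_centers[bin - 1];
            const double vj = v_centers[j];
            // window in U via the per-cp sort order (binary search)
            const int* ord = &ordU(0, c);
            auto cmp_lo = [&](int a, double val) { return U(a, c) < val; };
            const int* lo = std::lower_bound(ord, ord + n, ub - supp,
                                             cmp_lo);
            idxbuf.clear();
            for (const int* p = lo; p != ord + n; ++p) {
              const R_xlen_t i = *p;
              const double uu = U(i, c);
              if (uu > ub + supp) break;
              if (std::fabs(V(i, c) - vj) >= supp) continue;
              if (T(i, c) <= 0.0) continue;
              idxbuf.push_back(i);
            }
            double f_old = 0.0, f_new = 0.0;
            std::vector<double> dd(idxbuf.size());
            for (size_t q = 0; q < idxbuf.size(); ++q) {
              const R_xlen_t i = idxbuf[q];
              const double km = kern1d(U(i, c) - ub, kk, r, pitch) *
                                kern1d(V(i, c) - vj, kk, r, pitch);
              dd[q] = out_scale * delta * T(i, c) * km;
              const int mk = memb_mask[i];
              f_old += vox_penalty(dose[i], mk, obj_kind, obj_w, obj_level,
                                   fall_col, fall_t, i);
              f_new += vox_penalty(dose[i] + dd[q], mk, obj_kind, obj_w,
                                   obj_level, fall_col, fall_t, i);
            }
            if (f_new < f_old - 1e-12) {
              for (size_t q = 0; q < idxbuf.size(); ++q)
                dose[idxbuf[q]] += dd[q];
              if (side == 0) il(j, c) -= dir; else ir(j, c) += dir;
              ++n_acc;
              df_total += f_new - f_old;
            } else {
              break; // stop stepping this direction
            }
          }
        }
      }
    }
  }
  return List::create(_["il"] = il, _["ir"] = ir, _["dose"] = dose,
                      _["n_accepted"] = n_acc, _["df"] = df_total);
}
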