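#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Nearest-neighbour density lookup at world position (mm); outside grid -> 0.
static inline double density_at(const double* dens, const int* dims,
                                const double* sp, const double* org,
                                double px, double py, double pz) {
  const int ix = (int)std::lround((px - org[0]) / sp[0]);
  const int iy = (int)std::lround((py - org[1]) / sp[1]);
  const int iz = (int)std::lround((pz - org[2]) / sp[2]);
  if (ix < 0 || iy < 0 || iz < 0 || ix >= dims[0] || iy >= dims[1] || iz >= dims[2])
    return 0.0;
  return dens[ix + (R_xlen_t)dims[0] * (iy + (R_xlen_t)dims[1] * iz)];
}

// Clip the segment s -> p against the grid bounding box (voxel-centre box
// expanded by half a voxel); returns [t0, t1] in mm along the segment.
static inline void clip_to_grid(const double* sp, const double* org,
                                const int* dims, const double* s,
                                const double* dir, double len,
                                double& t0, double& t1) {
  t0 = 0.0;
  t1 = len;
  for (int a = 0; a < 3; ++a) {
    const double lo = org[a] - 0.5 * sp[a];
    const double hi = org[a] + (dims[a] - 0.5) * sp[a];
    if (std::fabs(dir[a]) < 1e-12) {
      if (s[a] < lo || s[a] > hi) { t0 = len; t1 = 0.0; return; }
    } else {
      double ta = (lo - s[a]) / dir[a];
      double tb = (hi - s[a]) / dir[a];
      if (ta > tb) std::swap(ta, tb);
      t0 = std::max(t0, ta);
      t1 = std::min(t1, tb);
    }
  }
}

static double ray_depth_mm(const double* dens, const int* dims, const double* sp,
                           const double* org, const double* src,
                           const double* pt, double step_mm) {
  double dir[3] = {pt[0] - src[0], pt[1] - src[1], pt[2] - src[2]};
  const double len = std::sqrt(dir[0] * dir[0] + dir[1] * dir[1] + dir[2] * dir[2]);
  if (len < 1e-9) return 0.0;
  for (int a = 0; a < 3; ++a) dir[a] /= len;
  double t0, t1;
  clip_to_grid(sp, org, dims, src, dir, len, t0, t1);
  if (t1 <= t0) return 0.0;
  const int nstep = (int)std::ceil((t1 - t0) / step_mm);
  const double h = (t1 - t0) / nstep;
  double acc = 0.0;
  for (int i = 0; i < nstep; ++i) {
    const double t = t0 + (i + 0.5) * h;
    acc += density_at(dens, dims, sp, org,
                      src[0] + dir[0] * t, src[1] + dir[1] * t,
                      src[2] + dir[2] * t);
  }
  return acc * h;
}

// Water-equivalent radiological depth (cm) from a source point to each
// target point, by uniform-step sampling of the density grid.
// [[Rcpp::export]]
NumericVector cpp_ray_depth(const NumericVector& density, const IntegerVector& dims,
                            const NumericVector& spacing, const NumericVector& origin,
                            const NumericVector& src, const NumericMatrix& pts,
                            double step_mm) {
  const int n = pts.nrow();
  NumericVector out(n);
  int d[3] = {dims[0], dims[1], dims[2]};
  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  double org[3] = {origin[0], origin[1], origin[2]};
  double s[3] = {src[0], src[1], src[2]};
  for (int i = 0; i < n; ++i) {
    double p[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    out[i] = ray_depth_mm(density.begin(), d, sp, org, s, p, step_mm) / 10.0;
  }
  return out;
}

// Per-voxel, per-control-point transfer terms of the pencil-beam kernel:
//   T = exp(-mu * d_rad_cm) * (SAD / |p - s|)^2
// plus the beam's-eye-view coordinates (u, v) of the voxel projected to the
// isocentre plane in the (collimator-rotated) fluence frame.
// vox_idx: 0-based linear indices of scoring voxels.
// [[Rcpp::export]]
List cpp_build_transfer(const NumericVector& density, const IntegerVector& dims,
                        const NumericVector& spacing, const NumericVector& origin,
                        const IntegerVector& vox_idx, const NumericMatrix& src,
                        const NumericMatrix& eu, const NumericMatrix& ev,
                        const NumericMatrix& ew, double sad_mm,
                        double mu_per_cm, double step_mm) {
  const R_xlen_t n = vox_idx.size();
  const int ncp = src.nrow();
  NumericMatrix T(n, ncp), U(n, ncp), V(n, ncp);
  int d[3] = {dims[0], dims[1], dims[2]};
  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  double org[3] = {origin[0], origin[1], origin[2]};
  const double* dens = density.begin();

  for (int c = 0; c < ncp; ++c) {
    double s[3] = {src(c, 0), src(c, 1), src(c, 2)};
    double exu[3] = {eu(c, 0), eu(c, 1), eu(c, 2)};
    double exv[3] = {ev(c, 0), ev(c, 1), ev(c, 2)};
    double exw[3] = {ew(c, 0), ew(c, 1), ew(c, 2)};
    for (R_xlen_t i = 0; i < n; ++i) {
      const R_xlen_t idx = vox_idx[i];
      const int ix = (int)(idx % d[0]);
      const int iy = (int)((idx / d[0]) % d[1]);
      const int iz = (int)(idx / ((R_xlen_t)d[0] * d[1]));
      double p[3] = {org[0] + ix * sp[0], org[1] + iy * sp[1], org[2] + iz * sp[2]};
      double vec[3] = {p[0] - s[0], p[1] - s[1], p[2] - s[2]};
      const double w = vec[0] * exw[0] + vec[1] * exw[1] + vec[2] * exw[2];
      if (w <= 1.0) { T(i, c) = 0.0; continue; }
      const double r2 = vec[0] * vec[0] + vec[1] * vec[1] + vec[2] * vec[2];
      U(i, c) = (vec[0] * exu[0] + vec[1] * exu[1] + vec[2] * exu[2]) * sad_mm / w;
      V(i, c) = (vec[0] * exv[0] + vec[1] * exv[1] + vec[2] * exv[2]) * sad_mm / w;
      const double depth_cm = ray_depth_mm(dens, d, sp, org, s, p, step_mm) / 10.0;
      T(i, c) = std::exp(-mu_per_cm * depth_cm) * (sad_mm * sad_mm / r2);
    }
  }
  return List::create(_["T"] = T, _["U"] = U, _["V"] = V);
}

// Forward projection: dose_i = sum_c T(i,c) * bilinear(fluence[,,c] at (U,V)).
// Fluence grid: nu x nv x ncp, bin centres u0 + j*du, v0 + k*dv.
// [[Rcpp::export]]
NumericVector cpp_forward(const NumericMatrix& T, const NumericMatrix& U,
                          const NumericMatrix& V, const NumericVector& fluence,
                          int nu, int nv, double u0, double du,
                          double v0, double dv) {
  const R_xlen_t n = T.nrow();
  const int ncp = T.ncol();
  NumericVector dose(n);
  const double* fl = fluence.begin();
  for (int c = 0; c < ncp; ++c) {
    const double* flc = fl + (R_xlen_t)nu * nv * c;
    for (R_xlen_t i = 0; i < n; ++i) {
      const double t = T(i, c);
      if (t <= 0.0) continue;
      const double gu = (U(i, c) - u0) / du;
      const double gv = (V(i, c) - v0) / dv;
      const int ju = (int)std::floor(gu);
      const int jv = (int)std::floor(gv);
      if (ju < -1 || jv < -1 || ju > nu - 1 || jv > nv - 1) continue;
      const double fu = gu - ju, fv = gv - jv;
      double acc = 0.0;
      for (int a = 0; a <= 1; ++a) {
        const int uu = ju + a;
        if (uu < 0 || uu >= nu) continue;
        const double wa = a ? fu : 1.0 - fu;
        for (int b = 0; b <= 1; ++b) {
          const int vv = jv + b;
          if (vv < 0 || vv >= nv) continue;
          const double wb = b ? fv : 1.0 - fv;
          acc += wa * wb * flc[uu + (R_xlen_t)nu * vv];
        }
      }
      dose[i] += t * acc;
    }
  }
  return dose;
}

// Adjoint of cpp_forward: scatter per-voxel residuals into the fluence grid.
// [[Rcpp::export]]
NumericVector cpp_backproject(const NumericMatrix& T, const NumericMatrix& U,
                              const NumericMatrix& V, const NumericVector& resid,
                              int nu, int nv, double u0, double du,
                              double v0, double dv) {
  const R_xlen_t n = T.nrow();
  const int ncp = T.ncol();
  NumericVector grad((R_xlen_t)nu * nv * ncp);
  double* g = grad.begin();
  for (int c = 0; c < ncp; ++c) {
    double* gc = g + (R_xlen_t)nu * nv * c;
    for (R_xlen_t i = 0; i < n; ++i) {
      const double r = resid[i];
      if (r == 0.0) continue;
      const double t = T(i, c);
      if (t <= 0.0) continue;
      const double gu = (U(i, c) - u0) / du;
      const double gv = (V(i, c) - v0) / dv;
      const int ju = (int)std::floor(gu);
      const int jv = (int)std::floor(gv);
      if (ju < -1 || jv < -1 || ju > nu - 1 || jv > nv - 1) continue;
      const double fu = gu - ju, fv = gv - jv;
      const double rt = r * t;
      for (int a = 0; a <= 1; ++a) {
        const int uu = ju + a;
        if (uu < 0 || uu >= nu) continue;
        const double wa = a ? fu : 1.0 - fu;
        for (int b = 0; b <= 1; ++b) {
          const int vv = jv + b;
          if (vv < 0 || vv >= nv) continue;
          const double wb = b ? fv : 1.0 - fv;
          gc[uu + (R_xlen_t)nu * vv] += rt * wa * wb;
        }
      }
    }
  }
  return grad;
}

// Trilinear resampling of a scalar grid at arbitrary world points (mm);
// outside the grid -> 0.
// [[Rcpp::export]]
NumericVector cpp_resample(const NumericVector& vals, const IntegerVector& dims,
                           const NumericVector& spacing, const NumericVector& origin,
                           const NumericMatrix& pts) {
  const int n = pts.nrow();
  NumericVector out(n);
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double* v = vals.begin();
  for (int i = 0; i < n; ++i) {
    const double gx = (pts(i, 0) - origin[0]) / spacing[0];
    const double gy = (pts(i, 1) - origin[1]) / spacing[1];
    const double gz = (pts(i, 2) - origin[2]) / spacing[2];
    const int jx = (int)std::floor(gx), jy = (int)std::floor(gy),
              jz = (int)std::floor(gz);
    double acc = 0.0;
    const double fx = gx - jx, fy = gy - jy, fz = gz - jz;
    for (int a = 0; a <= 1; ++a) {
      const int xx = jx + a;
      if (xx < 0 || xx >= nx) continue;
      const double wa = a ? fx : 1.0 - fx;
      for (int b = 0; b <= 1; ++b) {
        const int yy = jy + b;
        if (yy < 0 || yy >= ny) continue;
        const double wb = b ? fy : 1.0 - fy;
        for (int cc = 0; cc <= 1; ++cc) {
          const int zz = jz + cc;
          if (zz < 0 || zz >= nz) continue;
          const double wc = cc ? fz : 1.0 - fz;
          acc += wa * wb * wc *
                 v[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)];
        }
      }
    }
    out[i] = acc;
  }
  return out;
}
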