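#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Trilinear / nearest resampling of a 3D array at arbitrary voxel coordinates.
// src: column-major array with dimensions sdim; mapi/mapj/mapk: 0-based voxel
// coordinates into src, one entry per output voxel. Samples outside the grid
// take `fill` unless clamp_edge is true, in which case coordinates are clamped
// to the volume boundary (used by the registration loop to avoid edge forces).
// [[Rcpp::export]]
NumericVector cpp_resample(const NumericVector& src, const IntegerVector& sdim,
                           const NumericVector& mapi, const NumericVector& mapj,
                           const NumericVector& mapk, const bool nearest,
                           const double fill, const bool clamp_edge) {
  const int nx = sdim[0], ny = sdim[1], nz = sdim[2];
  const R_xlen_t n = mapi.size();
  NumericVector out(n);
  const double* s = src.begin();
  for (R_xlen_t t = 0; t < n; ++t) {
    double x = mapi[t], y = mapj[t], z = mapk[t];
    if (clamp_edge) {
      x = std::min(std::max(x, 0.0), (double)(nx - 1));
      y = std::min(std::max(y, 0.0), (double)(ny - 1));
      z = std::min(std::max(z, 0.0), (double)(nz - 1));
    }
    if (nearest) {
      int i = (int)std::lround(x), j = (int)std::lround(y), k = (int)std::lround(z);
      if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) {
        out[t] = fill;
      } else {
        out[t] = s[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
      }
      continue;
    }
    if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
      out[t] = fill;
      continue;
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 == nx - 1) i0--;
    if (j0 == ny - 1) j0--;
    if (k0 == nz - 1) k0--;
    if (i0 < 0) i0 = 0;
    if (j0 < 0) j0 = 0;
    if (k0 < 0) k0 = 0;
    const double fx = x - i0, fy = y - j0, fz = z - k0;
    const R_xlen_t base = i0 + (R_xlen_t)nx * (j0 + (R_xlen_t)ny * k0);
    const R_xlen_t dx = 1, dy = nx, dz = (R_xlen_t)nx * ny;
    const double c000 = s[base],            c100 = s[base + dx];
    const double c010 = s[base + dy],       c110 = s[base + dx + dy];
    const double c001 = s[base + dz],       c101 = s[base + dx + dz];
    const double c011 = s[base + dy + dz],  c111 = s[base + dx + dy + dz];
    const double c00 = c000 * (1 - fx) + c100 * fx;
    const double c10 = c010 * (1 - fx) + c110 * fx;
    const double c01 = c001 * (1 - fx) + c101 * fx;
    const double c11 = c011 * (1 - fx) + c111 * fx;
    const double c0 = c00 * (1 - fy) + c10 * fy;
    const double c1 = c01 * (1 - fy) + c11 * fy;
    out[t] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// Separable Gaussian smoothing with reflecting boundaries; sigma per axis in
// voxel units. Axes with sigma below 0.05 voxels are skipped.
static void smooth_axis(std::vector<double>& a, const int nx, const int ny,
                        const int nz, const int axis, const double sigma) {
  if (sigma < 0.05) return;
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * r + 1);
  double ksum = 0.0;
  for (int i = -r; i <= r; ++i) {
    ker[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    ksum += ker[i + r];
  }
  for (double& k : ker) k /= ksum;
  const int n[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  const int na = n[axis];
  const R_xlen_t sa = stride[axis];
  std::vector<double> line(na), out(na);
  // iterate over all lines along `axis`
  const int b1 = axis == 0 ? 1 : 0;
  const int b2 = axis == 2 ? 1 : 2;
  const int lo = std::min(r, na);
  const int hi = std::max(lo, na - r);
  for (int q = 0; q < n[b2]; ++q) {
    for (int p = 0; p < n[b1]; ++p) {
      const R_xlen_t off = (R_xlen_t)p * stride[b1] + (R_xlen_t)q * stride[b2];
      for (int i = 0; i < na; ++i) line[i] = a[off + (R_xlen_t)i * sa];
      // interior: branch-free
      for (int i = lo; i < hi; ++i) {
        double acc = 0.0;
        const double* lp = &line[i - r];
        for (int d = 0; d <= 2 * r; ++d) acc += ker[d] * lp[d];
        out[i] = acc;
      }
      // borders: reflecting indices
      for (int pass = 0; pass < 2; ++pass) {
        const int s0 = pass == 0 ? 0 : hi;
        const int s1 = pass == 0 ? lo : na;
        for (int i = s0; i < s1; ++i) {
          double acc = 0.0;
          for (int d = -r; d <= r; ++d) {
            int idx = i + d;
            if (idx < 0) idx = -idx;               // reflect
            if (idx >= na) idx = 2 * na - 2 - idx;
            idx = clampi(idx, 0, na - 1);
            acc += ker[d + r] * line[idx];
          }
          out[i] = acc;
        }
      }
      for (int i = 0; i < na; ++i) a[off + (R_xlen_t)i * sa] = out[i];
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_gaussian3d(const NumericVector& arr, const IntegerVector& dim,
                             const NumericVector& sigma_vox) {
  std::vector<double> a(arr.begin(), arr.end());
  smooth_axis(a, dim[0], dim[1], dim[2], 0, sigma_vox[0]);
  smooth_axis(a, dim[0], dim[1], dim[2], 1, sigma_vox[1]);
  smooth_axis(a, dim[0], dim[1], dim[2], 2, sigma_vox[2]);
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// One resolution level of the additive demons loop with dual Gaussian
// regularisation. fixed/moving share the grid; f* are the current field
// components in mm; returns updated field plus the MSE trace.
// [[Rcpp::export]]
List cpp_demons_level(const NumericVector& fixed, const NumericVector& moving,
                      const IntegerVector& dim, const NumericVector& spacing,
                      NumericVector fx, NumericVector fy, NumericVector fz,
                      const int max_iter, const double update_sigma_mm,
                      const double field_sigma_mm, const double max_step_mm,
                      const double tol, const NumericVector& mask) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double smean = (sx + sy + sz) / 3.0;
  const double kappa = smean * smean;
  const bool use_mask = mask.size() == n;
  std::vector<double> Fx(fx.begin(), fx.end()), Fy(fy.begin(), fy.end()),
      Fz(fz.begin(), fz.end());
  std::vector<double> Px(Fx), Py(Fy), Pz(Fz);  // last accepted field
  std::vector<double> warped(n), ux(n), uy(n), uz(n);
  std::vector<double> mse_trace;
  const double* fim = fixed.begin();
  const double* mim = moving.begin();
  NumericVector mi(n), mj(n), mk(n);
  double prev_mse = R_PosInf;
  int it;
  for (it = 0; it < max_iter; ++it) {
    // warp moving by current field (clamped trilinear)
    {
      R_xlen_t t = 0;
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
          for (int i = 0; i < nx; ++i, ++t) {
            mi[t] = i + Fx[t] / sx;
            mj[t] = j + Fy[t] / sy;
            mk[t] = k + Fz[t] / sz;
          }
    }
    NumericVector w = cpp_resample(moving, dim, mi, mj, mk, false, 0.0, true);
    std::copy(w.begin(), w.end(), warped.begin());
    double mse = 0.0;
    for (R_xlen_t t = 0; t < n; ++t) {
      const double d = warped[t] - fim[t];
      mse += d * d;
    }
    mse /= (double)n;
    if (it > 0 && mse > prev_mse) {
      // last update made things worse: revert it and stop the level, so the
      // accepted-field MSE trace is non-increasing
      Fx = Px; Fy = Py; Fz = Pz;
      break;
    }
    mse_trace.push_back(mse);
    if (it > 0 && prev_mse > 0 &&
        (prev_mse - mse) / prev_mse < tol) {
      break;
    }
    prev_mse = mse;
    Px = Fx; Py = Fy; Pz = Fz;
    // gradient of warped moving (central differences, one-sided at borders)
    R_xlen_t t = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i, ++t) {
          const int ip = clampi(i + 1, 0, nx - 1), im = clampi(i - 1, 0, nx - 1);
          const int jp = clampi(j + 1, 0, ny - 1), jm = clampi(j - 1, 0, ny - 1);
          const int kp = clampi(k + 1, 0, nz - 1), km = clampi(k - 1, 0, nz - 1);
          const double gx = (warped[ip + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] -
                             warped[im + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)]) /
                            ((ip - im) * sx);
          const double gy = (warped[i + (R_xlen_t)nx * (jp + (R_xlen_t)ny * k)] -
                             warped[i + (R_xlen_t)nx * (jm + (R_xlen_t)ny * k)]) /
                            ((jp - jm) * sy);
          const double gz = (warped[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * kp)] -
                             warped[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * km)]) /
                            ((kp - km) * sz);
          const double diff = warped[t] - fim[t];
          const double denom = gx * gx + gy * gy + gz * gz + diff * diff / kappa;
          double vx = 0, vy = 0, vz = 0;
          if (denom > 1e-12) {
            const double fac = -diff / denom;  // descent direction on 0.5*diff^2
            vx = fac * gx;
            vy = fac * gy;
            vz = fac * gz;
            const double nrm = std::sqrt(vx * vx + vy * vy + vz * vz);
            if (nrm > max_step_mm) {
              const double sc = max_step_mm / nrm;
              vx *= sc; vy *= sc; vz *= sc;
            }
          }
          if (use_mask) {
            vx *= mask[t]; vy *= mask[t]; vz *= mask[t];
          }
          ux[t] = vx; uy[t] = vy; uz[t] = vz;
        }
    smooth_axis(ux, nx, ny, nz, 0, update_sigma_mm / sx);
    smooth_axis(ux, nx, ny, nz, 1, update_sigma_mm / sy);
    smooth_axis(ux, nx, ny, nz, 2, update_sigma_mm / sz);
    smooth_axis(uy, nx, ny, nz, 0, update_sigma_mm / sx);
    smooth_axis(uy, nx, ny, nz, 1, update_sigma_mm / sy);
    smooth_axis(uy, nx, ny, nz, 2, update_sigma_mm / sz);
    smooth_axis(uz, nx, ny, nz, 0, update_sigma_mm / sx);
    smooth_axis(uz, nx, ny, nz, 1, update_sigma_mm / sy);
    smooth_axis(uz, nx, ny, nz, 2, update_sigma_mm / sz);
    for (R_xlen_t t2 = 0; t2 < n; ++t2) {
      Fx[t2] += ux[t2];
      Fy[t2] += uy[t2];
      Fz[t2] += uz[t2];
    }
    smooth_axis(Fx, nx, ny, nz, 0, field_sigma_mm / sx);
    smooth_axis(Fx, nx, ny, nz, 1, field_sigma_mm / sy);
    smooth_axis(Fx, nx, ny, nz, 2, field_sigma_mm / sz);
    smooth_axis(Fy, nx, ny, nz, 0, field_sigma_mm / sx);
    smooth_axis(Fy, nx, ny, nz, 1, field_sigma_mm / sy);
    smooth_axis(Fy, nx, ny, nz, 2, field_sigma_mm / sz);
    smooth_axis(Fz, nx, ny, nz, 0, field_sigma_mm / sx);
    smooth_axis(Fz, nx, ny, nz, 1, field_sigma_mm / sy);
    smooth_axis(Fz, nx, ny, nz, 2, field_sigma_mm / sz);
  }
  NumericVector ofx(Fx.begin(), Fx.end()), ofy(Fy.begin(), Fy.end()),
      ofz(Fz.begin(), Fz.end());
  ofx.attr("dim") = dim; ofy.attr("dim") = dim; ofz.attr("dim") = dim;
  return List::create(_["fx"] = ofx, _["fy"] = ofy, _["fz"] = ofz,
                      _["mse"] = NumericVector(mse_trace.begin(), mse_trace.end()),
                      _["iterations"] = (int)mse_trace.size());
}

// Jacobian determinant of the mapping x -> x + f(x) by central differences;
// border voxels are assigned 1.
// [[Rcpp::export]]
NumericVector cpp_jacobian_det(const NumericVector& fx, const NumericVector& fy,
                               const NumericVector& fz, const IntegerVector& dim,
                               const NumericVector& spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  NumericVector out((R_xlen_t)nx * ny * nz, 1.0);
  const double* FX = fx.begin();
  const double* FY = fy.begin();
  const double* FZ = fz.begin();
  for (int k = 1; k < nz - 1; ++k)
    for (int j = 1; j < ny - 1; ++j)
      for (int i = 1; i < nx - 1; ++i) {
        const R_xlen_t t = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        const R_xlen_t dx = 1, dy = nx, dz = (R_xlen_t)nx * ny;
        const double a11 = 1 + (FX[t + dx] - FX[t - dx]) / (2 * sx);
        const double a12 = (FX[t + dy] - FX[t - dy]) / (2 * sy);
        const double a13 = (FX[t + dz] - FX[t - dz]) / (2 * sz);
        const double a21 = (FY[t + dx] - FY[t - dx]) / (2 * sx);
        const double a22 = 1 + (FY[t + dy] - FY[t - dy]) / (2 * sy);
        const double a23 = (FY[t + dz] - FY[t - dz]) / (2 * sz);
        const double a31 = (FZ[t + dx] - FZ[t - dx]) / (2 * sx);
        const double a32 = (FZ[t + dy] - FZ[t - dy]) / (2 * sy);
        const double a33 = 1 + (FZ[t + dz] - FZ[t - dz]) / (2 * sz);
        out[t] = a11 * (a22 * a33 - a23 * a32) - a12 * (a21 * a33 - a23 * a31) +
                 a13 * (a21 * a32 - a22 * a31);
      }
  out.attr("dim") = dim;
  return out;
}

// 6-connected component labelling of a binary mask.
// [[Rcpp::export]]
IntegerVector cpp_label3d(const IntegerVector& mask, const IntegerVector& dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int cur = 0;
  std::vector<R_xlen_t> stack;
  const R_xlen_t dxs[6] = {1, -1, (R_xlen_t)nx, -(R_xlen_t)nx,
                           (R_xlen_t)nx * ny, -(R_xlen_t)nx * ny};
  for (R_xlen_t t0 = 0; t0 < n; ++t0) {
    if (mask[t0] == 0 || lab[t0] != 0) continue;
    ++cur;
    stack.clear();
    stack.push_back(t0);
    lab[t0] = cur;
    while (!stack.empty()) {
      const R_xlen_t t = stack.back();
      stack.pop_back();
      const int i = (int)(t % nx);
      const int j = (int)((t / nx) % ny);
      const int k = (int)(t / ((R_xlen_t)nx * ny));
      for (int d = 0; d < 6; ++d) {
        if (d == 0 && i == nx - 1) continue;
        if (d == 1 && i == 0) continue;
        if (d == 2 && j == ny - 1) continue;
        if (d == 3 && j == 0) continue;
        if (d == 4 && k == nz - 1) continue;
        if (d == 5 && k == 0) continue;
        const R_xlen_t u = t + dxs[d];
        if (mask[u] != 0 && lab[u] == 0) {
          lab[u] = cur;
          stack.push_back(u);
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Two-pass 26-neighbour chamfer distance transform (approximate Euclidean, in
// mm) to the nearest mask voxel; 0 inside the mask.
// [[Rcpp::export]]
NumericVector cpp_chamfer_dt(const IntegerVector& mask, const IntegerVector& dim,
                             const NumericVector& spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double big = 1e30;
  std::vector<double> d(n);
  for (R_xlen_t t = 0; t < n; ++t) d[t] = mask[t] != 0 ? 0.0 : big;
  // neighbour offsets with di+dj*3+dk*9 ordering; forward = negative half
  struct Off { int di, dj, dk; double w; };
  std::vector<Off> fwd;
  for (int dk = -1; dk <= 0; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (dk == 0 && (dj > 0 || (dj == 0 && di >= 0))) continue;
        const double w = std::sqrt(di * di * spacing[0] * spacing[0] +
                                   dj * dj * spacing[1] * spacing[1] +
                                   dk * dk * spacing[2] * spacing[2]);
        fwd.push_back({di, dj, dk, w});
      }
  // forward pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t t = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        if (d[t] == 0.0) continue;
        double best = d[t];
        for (const Off& o : fwd) {
          const int ii = i + o.di, jj = j + o.dj, kk = k + o.dk;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            continue;
          const double cand = d[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)] + o.w;
          if (cand < best) best = cand;
        }
        d[t] = best;
      }
  // backward pass
  for (int k = nz - 1; k >= 0; --k)
    for (int j = ny - 1; j >= 0; --j)
      for (int i = nx - 1; i >= 0; --i) {
        const R_xlen_t t = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        if (d[t] == 0.0) continue;
        double best = d[t];
        for (const Off& o : fwd) {
          const int ii = i - o.di, jj = j - o.dj, kk = k - o.dk;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            continue;
          const double cand = d[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)] + o.w;
          if (cand < best) best = cand;
        }
        d[t] = best;
      }
  NumericVector out(d.begin(), d.end());
  out.attr("dim") = dim;
  return out;
}
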