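#include <Rcpp.h>
#include <cmath>
#include <unordered_map>
using namespace Rcpp;

// Linear index into a column-major nx*ny*nz array.
static inline R_xlen_t lin(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

static inline double fetch(const double* v, int i, int j, int k,
                           int nx, int ny, int nz) {
  if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return 0.0;
  return v[lin(i, j, k, nx, ny)];
}

// Trilinear sampling at continuous 0-based voxel coordinates.
// Out-of-bounds corners contribute 0 (background fill).
// [[Rcpp::export]]
NumericVector cpp_sample_linear(NumericVector values, IntegerVector dims,
                                NumericMatrix pts) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double* v = values.begin();
  const R_xlen_t n = pts.nrow();
  NumericVector out(n);
  for (R_xlen_t p = 0; p < n; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (!R_finite(x) || !R_finite(y) || !R_finite(z)) { out[p] = 0.0; continue; }
    if (x < -1.0 || y < -1.0 || z < -1.0 ||
        x > (double)nx || y > (double)ny || z > (double)nz) { out[p] = 0.0; continue; }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    double fx = x - i0, fy = y - j0, fz = z - k0;
    double c00 = fetch(v, i0, j0, k0, nx, ny, nz) * (1 - fx) +
                 fetch(v, i0 + 1, j0, k0, nx, ny, nz) * fx;
    double c10 = fetch(v, i0, j0 + 1, k0, nx, ny, nz) * (1 - fx) +
                 fetch(v, i0 + 1, j0 + 1, k0, nx, ny, nz) * fx;
    double c01 = fetch(v, i0, j0, k0 + 1, nx, ny, nz) * (1 - fx) +
                 fetch(v, i0 + 1, j0, k0 + 1, nx, ny, nz) * fx;
    double c11 = fetch(v, i0, j0 + 1, k0 + 1, nx, ny, nz) * (1 - fx) +
                 fetch(v, i0 + 1, j0 + 1, k0 + 1, nx, ny, nz) * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[p] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// Nearest-neighbour sampling; out-of-domain -> 0.
// [[Rcpp::export]]
NumericVector cpp_sample_nearest(NumericVector values, IntegerVector dims,
                                 NumericMatrix pts) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double* v = values.begin();
  const R_xlen_t n = pts.nrow();
  NumericVector out(n);
  for (R_xlen_t p = 0; p < n; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (!R_finite(x) || !R_finite(y) || !R_finite(z)) { out[p] = 0.0; continue; }
    int i = (int)std::lround(x), j = (int)std::lround(y), k = (int)std::lround(z);
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) out[p] = 0.0;
    else out[p] = v[lin(i, j, k, nx, ny)];
  }
  return out;
}

// Separable Gaussian smoothing, sigma per axis in voxels, kernel truncated at
// 3 sigma and renormalised over the in-bounds support (no edge dimming).
static void gauss_axis(std::vector<double>& a, std::vector<double>& tmp,
                       int nx, int ny, int nz, int axis, double sigma) {
  if (sigma <= 1e-8) return;
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> w(2 * r + 1);
  for (int t = -r; t <= r; ++t) w[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
  int n[3] = {nx, ny, nz};
  R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  int len = n[axis];
  R_xlen_t s = stride[axis];
  int u_ = (axis == 0) ? 1 : 0;
  int v_ = (axis == 2) ? 1 : 2;
  for (int c2 = 0; c2 < n[v_]; ++c2) {
    for (int c1 = 0; c1 < n[u_]; ++c1) {
      R_xlen_t base = (R_xlen_t)c1 * stride[u_] + (R_xlen_t)c2 * stride[v_];
      for (int i = 0; i < len; ++i) {
        double acc = 0.0, wsum = 0.0;
        int lo = std::max(-r, -i), hi = std::min(r, len - 1 - i);
        for (int t = lo; t <= hi; ++t) {
          acc += w[t + r] * a[base + (R_xlen_t)(i + t) * s];
          wsum += w[t + r];
        }
        tmp[base + (R_xlen_t)i * s] = acc / wsum;
      }
    }
  }
  a.swap(tmp);
}

// [[Rcpp::export]]
NumericVector cpp_gauss3(NumericVector arr, IntegerVector dims,
                         NumericVector sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> a(arr.begin(), arr.end()), tmp(a.size());
  for (int ax = 0; ax < 3; ++ax) gauss_axis(a, tmp, nx, ny, nz, ax, sigma[ax]);
  return NumericVector(a.begin(), a.end());
}

// Separable moving-window sum, window half-width r, zero-padded.
static void box_axis(std::vector<double>& a, std::vector<double>& tmp,
                     int nx, int ny, int nz, int axis, int r) {
  int n[3] = {nx, ny, nz};
  R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  int len = n[axis];
  R_xlen_t s = stride[axis];
  int u_ = (axis == 0) ? 1 : 0;
  int v_ = (axis == 2) ? 1 : 2;
  for (int c2 = 0; c2 < n[v_]; ++c2) {
    for (int c1 = 0; c1 < n[u_]; ++c1) {
      R_xlen_t base = (R_xlen_t)c1 * stride[u_] + (R_xlen_t)c2 * stride[v_];
      double run = 0.0;
      for (int i = 0; i <= std::min(r, len - 1); ++i) run += a[base + (R_xlen_t)i * s];
      for (int i = 0; i < len; ++i) {
        tmp[base + (R_xlen_t)i * s] = run;
        int add = i + r + 1, rem = i - r;
        if (add < len) run += a[base + (R_xlen_t)add * s];
        if (rem >= 0) run -= a[base + (R_xlen_t)rem * s];
      }
    }
  }
  a.swap(tmp);
}

// [[Rcpp::export]]
NumericVector cpp_boxsum3(NumericVector arr, IntegerVector dims, int radius) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> a(arr.begin(), arr.end()), tmp(a.size());
  for (int ax = 0; ax < 3; ++ax) box_axis(a, tmp, nx, ny, nz, ax, radius);
  return NumericVector(a.begin(), a.end());
}

// Central-difference gradient in world units (per micron); one-sided at faces.
// [[Rcpp::export]]
NumericMatrix cpp_grad3(NumericVector arr, IntegerVector dims,
                        NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double* v = arr.begin();
  NumericMatrix out(arr.size(), 3);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t id = lin(i, j, k, nx, ny);
        int ip = std::min(i + 1, nx - 1), im = std::max(i - 1, 0);
        int jp = std::min(j + 1, ny - 1), jm = std::max(j - 1, 0);
        int kp = std::min(k + 1, nz - 1), km = std::max(k - 1, 0);
        out(id, 0) = (v[lin(ip, j, k, nx, ny)] - v[lin(im, j, k, nx, ny)]) /
                     ((ip - im) * spacing[0]);
        out(id, 1) = (v[lin(i, jp, k, nx, ny)] - v[lin(i, jm, k, nx, ny)]) /
                     ((jp - jm) * spacing[1]);
        out(id, 2) = (v[lin(i, j, kp, nx, ny)] - v[lin(i, j, km, nx, ny)]) /
                     ((kp - km) * spacing[2]);
      }
  return out;
}

// For each row of a, the minimum Euclidean distance to any row of b.
// [[Rcpp::export]]
NumericVector cpp_min_dists(NumericMatrix a, NumericMatrix b) {
  const R_xlen_t na = a.nrow(), nb = b.nrow();
  NumericVector out(na);
  for (R_xlen_t i = 0; i < na; ++i) {
    double ax = a(i, 0), ay = a(i, 1), az = a(i, 2);
    double best = R_PosInf;
    for (R_xlen_t j = 0; j < nb; ++j) {
      double dx = ax - b(j, 0), dy = ay - b(j, 1), dz = az - b(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Per-row majority vote over integer labels; ties broken by smallest label.
// [[Rcpp::export]]
IntegerVector cpp_majority_vote(IntegerMatrix labels) {
  const R_xlen_t n = labels.nrow();
  const int m = labels.ncol();
  IntegerVector out(n);
  std::unordered_map<int, int> counts;
  for (R_xlen_t i = 0; i < n; ++i) {
    counts.clear();
    for (int j = 0; j < m; ++j) counts[labels(i, j)]++;
    int best_lab = labels(i, 0), best_cnt = -1;
    for (auto& kv : counts) {
      if (kv.second > best_cnt || (kv.second == best_cnt && kv.first < best_lab)) {
        best_cnt = kv.second;
        best_lab = kv.first;
      }
    }
    out[i] = best_lab;
  }
  return out;
}

// Joint histogram counts over [amin,amax] x [bmin,bmax]; values clipped to
// the range edges.
// [[Rcpp::export]]
NumericMatrix cpp_joint_hist(NumericVector a, NumericVector b, int bins,
                             double amin, double amax, double bmin, double bmax) {
  NumericMatrix h(bins, bins);
  const double aw = (amax - amin), bw = (bmax - bmin);
  const R_xlen_t n = a.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    int ia = aw > 0 ? (int)((a[i] - amin) / aw * bins) : 0;
    int ib = bw > 0 ? (int)((b[i] - bmin) / bw * bins) : 0;
    if (ia < 0) ia = 0;
    if (ib < 0) ib = 0;
    if (ia >= bins) ia = bins - 1;
    if (ib >= bins) ib = bins - 1;
    h(ia, ib) += 1.0;
  }
  return h;
}

static double samp1(const std::vector<double>& v, int nx, int ny, int nz,
                    double x, double y, double z);

// Mutual information (nats) between a fixed image and a rigidly resampled
// moving image, computed in one pass: for each fixed voxel the moving image
// is sampled at R (x - c) + c + t and binned into a joint histogram with the
// supplied intensity ranges (values clipped to range edges).
// [[Rcpp::export]]
double cpp_mi_rigid(NumericVector mvals, IntegerVector mdims,
                    NumericVector mspacing, NumericVector morigin,
                    NumericVector fvals, IntegerVector fdims,
                    NumericVector fspacing, NumericVector forigin,
                    NumericMatrix rot, NumericVector trans,
                    NumericVector center, int bins, NumericVector frange,
                    NumericVector mrange) {
  const int nx = fdims[0], ny = fdims[1], nz = fdims[2];
  const int mx_ = mdims[0], my_ = mdims[1], mz_ = mdims[2];
  std::vector<double> m(mvals.begin(), mvals.end());
  std::vector<double> h((R_xlen_t)bins * bins, 0.0);
  const double fw = frange[1] - frange[0], mw = mrange[1] - mrange[0];
  if (fw <= 0 || mw <= 0) return 0.0;
  R_xlen_t id = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++id) {
        double x = forigin[0] + i * fspacing[0] - center[0];
        double y = forigin[1] + j * fspacing[1] - center[1];
        double z = forigin[2] + k * fspacing[2] - center[2];
        double px = rot(0, 0) * x + rot(0, 1) * y + rot(0, 2) * z + center[0] + trans[0];
        double py = rot(1, 0) * x + rot(1, 1) * y + rot(1, 2) * z + center[1] + trans[1];
        double pz = rot(2, 0) * x + rot(2, 1) * y + rot(2, 2) * z + center[2] + trans[2];
        double mv = samp1(m, mx_, my_, mz_, (px - morigin[0]) / mspacing[0],
                          (py - morigin[1]) / mspacing[1],
                          (pz - morigin[2]) / mspacing[2]);
        int bf = (int)((fvals[id] - frange[0]) / fw * bins);
        int bm = (int)((mv - mrange[0]) / mw * bins);
        if (bf < 0) bf = 0;
        if (bm < 0) bm = 0;
        if (bf >= bins) bf = bins - 1;
        if (bm >= bins) bm = bins - 1;
        h[bf + (R_xlen_t)bins * bm] += 1.0;
      }
  double n = (double)id;
  std::vector<double> px_(bins, 0.0), py_(bins, 0.0);
  for (int b2 = 0; b2 < bins; ++b2)
    for (int b1 = 0; b1 < bins; ++b1) {
      px_[b1] += h[b1 + (R_xlen_t)bins * b2];
      py_[b2] += h[b1 + (R_xlen_t)bins * b2];
    }
  double mi = 0.0;
  for (int b2 = 0; b2 < bins; ++b2)
    for (int b1 = 0; b1 < bins; ++b1) {
      double p = h[b1 + (R_xlen_t)bins * b2];
      if (p > 0) mi += p / n * std::log(p * n / (px_[b1] * py_[b2]));
    }
  return mi > 0 ? mi : 0.0;
}

// ---- symmetric diffeomorphic level driver ----------------------------------

// Trilinear sample of one array at continuous 0-based index coordinates.
static double samp1(const std::vector<double>& v, int nx, int ny, int nz,
                    double x, double y, double z) {
  if (x < -1.0 || y < -1.0 || z < -1.0 ||
      x > (double)nx || y > (double)ny || z > (double)nz) return 0.0;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  double fx = x - i0, fy = y - j0, fz = z - k0;
  auto f = [&](int i, int j, int k) -> double {
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return 0.0;
    return v[lin(i, j, k, nx, ny)];
  };
  double c00 = f(i0, j0, k0) * (1 - fx) + f(i0 + 1, j0, k0) * fx;
  double c10 = f(i0, j0 + 1, k0) * (1 - fx) + f(i0 + 1, j0 + 1, k0) * fx;
  double c01 = f(i0, j0, k0 + 1) * (1 - fx) + f(i0 + 1, j0, k0 + 1) * fx;
  double c11 = f(i0, j0 + 1, k0 + 1) * (1 - fx) + f(i0 + 1, j0 + 1, k0 + 1) * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

static void grad_inplace(const std::vector<double>& v, int nx, int ny, int nz,
                         const double* spacing, std::vector<double>& gx,
                         std::vector<double>& gy, std::vector<double>& gz) {
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t id = lin(i, j, k, nx, ny);
        int ip = std::min(i + 1, nx - 1), im = std::max(i - 1, 0);
        int jp = std::min(j + 1, ny - 1), jm = std::max(j - 1, 0);
        int kp = std::min(k + 1, nz - 1), km = std::max(k - 1, 0);
        gx[id] = (v[lin(ip, j, k, nx, ny)] - v[lin(im, j, k, nx, ny)]) /
                 ((ip - im) * spacing[0]);
        gy[id] = (v[lin(i, jp, k, nx, ny)] - v[lin(i, jm, k, nx, ny)]) /
                 ((jp - jm) * spacing[1]);
        gz[id] = (v[lin(i, j, kp, nx, ny)] - v[lin(i, j, km, nx, ny)]) /
                 ((kp - km) * spacing[2]);
      }
}

static void boxsum_inplace(std::vector<double>& a, std::vector<double>& tmp,
                           int nx, int ny, int nz, int r) {
  for (int ax = 0; ax < 3; ++ax) box_axis(a, tmp, nx, ny, nz, ax, r);
}

static void gauss_inplace(std::vector<double>& a, std::vector<double>& tmp,
                          int nx, int ny, int nz, double sigma) {
  for (int ax = 0; ax < 3; ++ax) gauss_axis(a, tmp, nx, ny, nz, ax, sigma);
}

// One resolution level of the greedy symmetric scheme. u1/u2 are the
// half-path displacement fields (world units, 3 columns), modified in place
// conceptually and returned. Images and fields share the level grid.
// [[Rcpp::export]]
List cpp_syn_level(NumericVector fvals, NumericVector mvals, IntegerVector dims,
                   NumericVector spacing, NumericMatrix u1_in,
                   NumericMatrix u2_in, int iters, int radius,
                   double sigma_update, double sigma_total, double cap,
                   int local_norm) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double sp[3] = {spacing[0], spacing[1], spacing[2]};
  std::vector<double> f(fvals.begin(), fvals.end());
  std::vector<double> m(mvals.begin(), mvals.end());
  std::vector<std::vector<double>> u1(3, std::vector<double>(n)),
      u2(3, std::vector<double>(n));
  for (int c = 0; c < 3; ++c)
    for (R_xlen_t i = 0; i < n; ++i) {
      u1[c][i] = u1_in(i, c);
      u2[c][i] = u2_in(i, c);
    }
  std::vector<double> fw(n), mw(n), tmp(n);
  std::vector<double> gx(n), gy(n), gz(n);
  std::vector<double> cnt(n), sa(n), sb(n), saa(n), sbb(n), sab(n);
  std::vector<std::vector<double>> frc(3, std::vector<double>(n));
  std::vector<std::vector<double>> delta(3, std::vector<double>(n));

  auto warp_half = [&](const std::vector<double>& img,
                       const std::vector<std::vector<double>>& u,
                       std::vector<double>& out) {
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          R_xlen_t id = lin(i, j, k, nx, ny);
          out[id] = samp1(img, nx, ny, nz, i + u[0][id] / sp[0],
                          j + u[1][id] / sp[1], k + u[2][id] / sp[2]);
        }
  };

  for (int it = 0; it < iters; ++it) {
    warp_half(f, u1, fw);
    warp_half(m, u2, mw);
    // windowed first/second moments
    std::fill(cnt.begin(), cnt.end(), 1.0);
    boxsum_inplace(cnt, tmp, nx, ny, nz, radius);
    sa = fw; boxsum_inplace(sa, tmp, nx, ny, nz, radius);
    sb = mw; boxsum_inplace(sb, tmp, nx, ny, nz, radius);
    for (R_xlen_t i = 0; i < n; ++i) saa[i] = fw[i] * fw[i];
    boxsum_inplace(saa, tmp, nx, ny, nz, radius);
    for (R_xlen_t i = 0; i < n; ++i) sbb[i] = mw[i] * mw[i];
    boxsum_inplace(sbb, tmp, nx, ny, nz, radius);
    for (R_xlen_t i = 0; i < n; ++i) sab[i] = fw[i] * mw[i];
    boxsum_inplace(sab, tmp, nx, ny, nz, radius);

    for (int side = 0; side < 2; ++side) {
      const std::vector<double>& img = side == 0 ? fw : mw;
      grad_inplace(img, nx, ny, nz, sp, gx, gy, gz);
      for (R_xlen_t i = 0; i < n; ++i) {
        double ma = sa[i] / cnt[i], mb = sb[i] / cnt[i];
        double A = sab[i] - ma * sb[i];
        double B = std::max(saa[i] - ma * sa[i], 0.0);
        double C = std::max(sbb[i] - mb * sb[i], 0.0);
        double denom = B * C;
        double coef = 0.0;
        if (denom > 1e-8) {
          double ra = fw[i] - ma, rb = mw[i] - mb;
          // ascent force on this side's half-map
          coef = side == 0 ? 2 * A / denom * (rb - A / B * ra)
                           : 2 * A / denom * (ra - A / C * rb);
        }
        frc[0][i] = coef * gx[i];
        frc[1][i] = coef * gy[i];
        frc[2][i] = coef * gz[i];
      }
      for (int c = 0; c < 3; ++c)
        gauss_inplace(frc[c], tmp, nx, ny, nz, sigma_update);
      double mx = 0.0;
      for (R_xlen_t i = 0; i < n; ++i) {
        double mag = frc[0][i] * frc[0][i] + frc[1][i] * frc[1][i] +
                     frc[2][i] * frc[2][i];
        if (mag > mx) mx = mag;
      }
      mx = std::sqrt(mx);
      if (mx < 1e-12) continue;
      if (local_norm) {
        // unit-flow update: strong-force voxels advance by ~cap, weak ones
        // (below 5% of the peak force) fade out proportionally
        double eps = 0.05 * mx;
        for (R_xlen_t i = 0; i < n; ++i) {
          double mag = std::sqrt(frc[0][i] * frc[0][i] + frc[1][i] * frc[1][i] +
                                 frc[2][i] * frc[2][i]);
          double sc = cap / (mag + eps);
          if (sc * mag > cap) sc = cap / mag;
          for (int c = 0; c < 3; ++c) delta[c][i] = frc[c][i] * sc;
        }
      } else {
        double sc = cap / mx;
        for (int c = 0; c < 3; ++c)
          for (R_xlen_t i = 0; i < n; ++i) delta[c][i] = frc[c][i] * sc;
      }
      // compose: u_new(x) = delta(x) + u(x + delta(x))
      std::vector<std::vector<double>>& u = side == 0 ? u1 : u2;
      for (int c = 0; c < 3; ++c) frc[c] = u[c];  // reuse frc as old-u copy
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
          for (int i = 0; i < nx; ++i) {
            R_xlen_t id = lin(i, j, k, nx, ny);
            double xi = i + delta[0][id] / sp[0];
            double yj = j + delta[1][id] / sp[1];
            double zk = k + delta[2][id] / sp[2];
            for (int c = 0; c < 3; ++c)
              u[c][id] = delta[c][id] + samp1(frc[c], nx, ny, nz, xi, yj, zk);
          }
      if (sigma_total > 1e-8)
        for (int c = 0; c < 3; ++c)
          gauss_inplace(u[c], tmp, nx, ny, nz, sigma_total);
    }
  }
  NumericMatrix u1_out(n, 3), u2_out(n, 3);
  for (int c = 0; c < 3; ++c)
    for (R_xlen_t i = 0; i < n; ++i) {
      u1_out(i, c) = u1[c][i];
      u2_out(i, c) = u2[c][i];
    }
  return List::create(_["u1"] = u1_out, _["u2"] = u2_out);
}

// Block-average downsampling over x and y by an integer factor (intensity).
// [[Rcpp::export]]
NumericVector cpp_block_mean_xy(NumericVector arr, IntegerVector dims,
                                int factor) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int mx = nx / factor, my = ny / factor;
  const double* v = arr.begin();
  NumericVector out((R_xlen_t)mx * my * nz);
  const double norm = 1.0 / (factor * factor);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < my; ++j)
      for (int i = 0; i < mx; ++i) {
        double acc = 0.0;
        for (int bj = 0; bj < factor; ++bj)
          for (int bi = 0; bi < factor; ++bi)
            acc += v[lin(i * factor + bi, j * factor + bj, k, nx, ny)];
        out[(R_xlen_t)i + (R_xlen_t)mx * ((R_xlen_t)j + (R_xlen_t)my * k)] = acc * norm;
      }
  return out;
}
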