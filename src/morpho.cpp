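// Low-level voxel routines for 3D morphometry on anisotropic grids.
// Array convention everywhere: R array with dim = (nz, ny, nx); linear
// index i = z + nz*(y + ny*x) (column-major, z fastest). Spacing is passed
// as the physical step along (z, y, x) in nm.

#include <Rcpp.h>
#include <queue>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

static inline R_xlen_t idx3(int z, int y, int x, int nz, int ny) {
  return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)x);
}

// 26-connected component labelling of a foreground mask.
// [[Rcpp::export]]
IntegerVector cc_label_3d(IntegerVector mask, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int z = (int)(cur % nz);
      R_xlen_t r = cur / nz;
      int y = (int)(r % ny);
      int x = (int)(r / ny);
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = x + dx; if (xx < 0 || xx >= nx) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy; if (yy < 0 || yy >= ny) continue;
          for (int dz = -1; dz <= 1; ++dz) {
            int zz = z + dz; if (zz < 0 || zz >= nz) continue;
            R_xlen_t q = idx3(zz, yy, xx, nz, ny);
            if (mask[q] != 0 && lab[q] == 0) { lab[q] = next; stack.push_back(q); }
          }
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Per-label voxel count, bounding box (0-based, inclusive) and centroid sums.
// [[Rcpp::export]]
DataFrame label_stats_cpp(IntegerVector lab, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  struct St { double n = 0, sz = 0, sy = 0, sx = 0;
              int z0 = INT_MAX, z1 = -1, y0 = INT_MAX, y1 = -1, x0 = INT_MAX, x1 = -1; };
  std::unordered_map<int, St> acc;
  R_xlen_t s = 0;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z, ++s) {
        int v = lab[s];
        if (v <= 0) continue;
        St &a = acc[v];
        a.n += 1; a.sz += z; a.sy += y; a.sx += x;
        if (z < a.z0) a.z0 = z; if (z > a.z1) a.z1 = z;
        if (y < a.y0) a.y0 = y; if (y > a.y1) a.y1 = y;
        if (x < a.x0) a.x0 = x; if (x > a.x1) a.x1 = x;
      }
  std::vector<int> keys;
  keys.reserve(acc.size());
  for (auto &kv : acc) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  int m = (int)keys.size();
  IntegerVector label(m), z0(m), z1(m), y0(m), y1(m), x0(m), x1(m);
  NumericVector cnt(m), mz(m), my(m), mx(m);
  for (int i = 0; i < m; ++i) {
    St &a = acc[keys[i]];
    label[i] = keys[i]; cnt[i] = a.n;
    mz[i] = a.sz / a.n; my[i] = a.sy / a.n; mx[i] = a.sx / a.n;
    z0[i] = a.z0; z1[i] = a.z1; y0[i] = a.y0; y1[i] = a.y1; x0[i] = a.x0; x1[i] = a.x1;
  }
  return DataFrame::create(_["label"] = label, _["n_voxels"] = cnt,
                           _["cz"] = mz, _["cy"] = my, _["cx"] = mx,
                           _["z0"] = z0, _["z1"] = z1, _["y0"] = y0, _["y1"] = y1,
                           _["x0"] = x0, _["x1"] = x1);
}

static void smooth_axis(std::vector<double> &a, std::vector<double> &tmp,
                        int nz, int ny, int nx, int axis, double sigma) {
  if (sigma <= 0) return;
  int rad = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * rad + 1);
  double ksum = 0;
  for (int i = -rad; i <= rad; ++i) { k[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma)); ksum += k[i + rad]; }
  for (auto &v : k) v /= ksum;
  int dims[3] = {nz, ny, nx};
  int nA = dims[axis];
  R_xlen_t str[3] = {1, (R_xlen_t)nz, (R_xlen_t)nz * ny};
  R_xlen_t s = str[axis];                      // contiguous inner block size
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  R_xlen_t nOuter = n / ((R_xlen_t)nA * s);
  // zero-padded boundary (callers pad their crops); inner loop contiguous
  for (R_xlen_t o = 0; o < nOuter; ++o) {
    R_xlen_t base = o * (R_xlen_t)nA * s;
    for (int t = 0; t < nA; ++t) {
      double *dst = &tmp[base + (R_xlen_t)t * s];
      for (R_xlen_t i = 0; i < s; ++i) dst[i] = 0.0;
      int lo = std::max(0, t - rad), hi = std::min(nA - 1, t + rad);
      for (int q = lo; q <= hi; ++q) {
        double w = k[q - t + rad];
        const double *src = &a[base + (R_xlen_t)q * s];
        for (R_xlen_t i = 0; i < s; ++i) dst[i] += w * src[i];
      }
    }
  }
  a.swap(tmp);
}

// Separable Gaussian smoothing; sigma given per axis (z, y, x) in voxels.
// [[Rcpp::export]]
NumericVector gauss_smooth_3d(NumericVector arr, IntegerVector dim, NumericVector sigma_zyx) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<double> a(arr.begin(), arr.end()), tmp(n);
  smooth_axis(a, tmp, nz, ny, nx, 0, sigma_zyx[0]);
  smooth_axis(a, tmp, nz, ny, nx, 1, sigma_zyx[1]);
  smooth_axis(a, tmp, nz, ny, nx, 2, sigma_zyx[2]);
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

static inline double tri_area(const double *p, const double *q, const double *r) {
  double ux = q[0] - p[0], uy = q[1] - p[1], uz = q[2] - p[2];
  double vx = r[0] - p[0], vy = r[1] - p[1], vz = r[2] - p[2];
  double cx = uy * vz - uz * vy, cy = uz * vx - ux * vz, cz = ux * vy - uy * vx;
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

// Iso-surface area by marching tetrahedra at `level` over a scalar field.
// spacing_zyx: physical step along (z, y, x). Returns area in spacing units^2.
// [[Rcpp::export]]
double mtetra_area(NumericVector f, IntegerVector dim, NumericVector spacing_zyx, double level) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  double sz = spacing_zyx[0], sy = spacing_zyx[1], sx = spacing_zyx[2];
  // cube vertex bitmask: bit0 = +z, bit1 = +y, bit2 = +x
  static const int tets[6][4] = {
    {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7}, {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};
  double total = 0.0;
  double P[8][3], val[8];
  for (int x = 0; x + 1 < nx; ++x)
    for (int y = 0; y + 1 < ny; ++y)
      for (int z = 0; z + 1 < nz; ++z) {
        bool anyAbove = false, anyBelow = false;
        for (int b = 0; b < 8; ++b) {
          int dz = b & 1, dy = (b >> 1) & 1, dx = (b >> 2) & 1;
          double v = f[idx3(z + dz, y + dy, x + dx, nz, ny)];
          val[b] = v;
          if (v > level) anyAbove = true; else anyBelow = true;
          P[b][0] = (x + dx) * sx; P[b][1] = (y + dy) * sy; P[b][2] = (z + dz) * sz;
        }
        if (!anyAbove || !anyBelow) continue;
        for (int t = 0; t < 6; ++t) {
          const int *tv = tets[t];
          int inside[4], nin = 0, out[4], nout = 0;
          for (int j = 0; j < 4; ++j) {
            if (val[tv[j]] > level) inside[nin++] = tv[j]; else out[nout++] = tv[j];
          }
          if (nin == 0 || nin == 4) continue;
          double E[4][3];
          auto interp = [&](int a, int b, double *dst) {
            double fa = val[a], fb = val[b];
            double tt = (level - fa) / (fb - fa);
            for (int c = 0; c < 3; ++c) dst[c] = P[a][c] + tt * (P[b][c] - P[a][c]);
          };
          if (nin == 1 || nin == 3) {
            int apex = (nin == 1) ? inside[0] : out[0];
            int *others = (nin == 1) ? out : inside;
            for (int j = 0; j < 3; ++j) interp(apex, others[j], E[j]);
            total += tri_area(E[0], E[1], E[2]);
          } else { // 2 in / 2 out -> quad
            interp(inside[0], out[0], E[0]);
            interp(inside[0], out[1], E[1]);
            interp(inside[1], out[1], E[2]);
            interp(inside[1], out[0], E[3]);
            total += tri_area(E[0], E[1], E[2]) + tri_area(E[0], E[2], E[3]);
          }
        }
      }
  return total;
}

// Count exposed voxel faces weighted by physical face area (brute-force
// surface estimator; used as an upper-bound oracle and single-voxel fallback).
// [[Rcpp::export]]
double voxel_face_area(IntegerVector mask, IntegerVector dim, NumericVector spacing_zyx) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  double sz = spacing_zyx[0], sy = spacing_zyx[1], sx = spacing_zyx[2];
  double az = sx * sy, ay = sx * sz, ax = sy * sz; // face areas normal to z, y, x
  double total = 0;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        if (mask[idx3(z, y, x, nz, ny)] == 0) continue;
        if (z == 0 || mask[idx3(z - 1, y, x, nz, ny)] == 0) total += az;
        if (z == nz - 1 || mask[idx3(z + 1, y, x, nz, ny)] == 0) total += az;
        if (y == 0 || mask[idx3(z, y - 1, x, nz, ny)] == 0) total += ay;
        if (y == ny - 1 || mask[idx3(z, y + 1, x, nz, ny)] == 0) total += ay;
        if (x == 0 || mask[idx3(z, y, x - 1, nz, ny)] == 0) total += ax;
        if (x == nx - 1 || mask[idx3(z, y, x + 1, nz, ny)] == 0) total += ax;
      }
  return total;
}

// 6-connected binary erosion, `iter` passes (out-of-grid counts as background).
// [[Rcpp::export]]
IntegerVector erode6(IntegerVector mask, IntegerVector dim, int iter) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<int> a(mask.begin(), mask.end()), b(n);
  for (int it = 0; it < iter; ++it) {
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y)
        for (int z = 0; z < nz; ++z) {
          R_xlen_t i = idx3(z, y, x, nz, ny);
          int keep = a[i];
          if (keep) {
            if (z == 0 || z == nz - 1 || y == 0 || y == ny - 1 || x == 0 || x == nx - 1) keep = 0;
            else if (!a[idx3(z - 1, y, x, nz, ny)] || !a[idx3(z + 1, y, x, nz, ny)] ||
                     !a[idx3(z, y - 1, x, nz, ny)] || !a[idx3(z, y + 1, x, nz, ny)] ||
                     !a[idx3(z, y, x - 1, nz, ny)] || !a[idx3(z, y, x + 1, nz, ny)]) keep = 0;
          }
          b[i] = keep;
        }
    a.swap(b);
  }
  IntegerVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}
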