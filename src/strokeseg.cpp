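#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// 3D connected-component labelling with 26-connectivity.
// mask: logical array of dim (nx, ny, nz); returns integer labels (0 = background),
// components numbered in scan order.
// [[Rcpp::export(name = ".cpp_label26")]]
IntegerVector cpp_label26(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  lab.attr("dim") = dims;
  std::vector<R_xlen_t> stack;
  int current = 0;
  for (R_xlen_t seed = 0; seed < n; ++seed) {
    if (!mask[seed] || lab[seed] != 0) continue;
    ++current;
    stack.clear();
    stack.push_back(seed);
    lab[seed] = current;
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / ((R_xlen_t)nx * ny));
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = z + dz;
        if (zz < 0 || zz >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int xx = x + dx;
            if (xx < 0 || xx >= nx) continue;
            R_xlen_t w = (R_xlen_t)xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
            if (mask[w] && lab[w] == 0) {
              lab[w] = current;
              stack.push_back(w);
            }
          }
        }
      }
    }
  }
  return lab;
}

static inline void chamfer_pass(std::vector<double> &d, int nx, int ny, int nz,
                                bool forward) {
  const double W1 = 1.0, W2 = std::sqrt(2.0), W3 = std::sqrt(3.0);
  // 13 half-neighbourhood offsets (the other 13 are covered by the reverse pass)
  const int off[13][3] = {
    {-1, 0, 0}, {0, -1, 0}, {0, 0, -1},
    {-1, -1, 0}, {-1, 1, 0}, {-1, 0, -1}, {-1, 0, 1}, {0, -1, -1}, {0, -1, 1},
    {-1, -1, -1}, {-1, -1, 1}, {-1, 1, -1}, {-1, 1, 1}
  };
  const double w[13] = {W1, W1, W1, W2, W2, W2, W2, W2, W2, W3, W3, W3, W3};
  int x0 = forward ? 0 : nx - 1, x1 = forward ? nx : -1, xs = forward ? 1 : -1;
  int y0 = forward ? 0 : ny - 1, y1 = forward ? ny : -1, ys = forward ? 1 : -1;
  int z0 = forward ? 0 : nz - 1, z1 = forward ? nz : -1, zs = forward ? 1 : -1;
  int sgn = forward ? 1 : -1;
  for (int z = z0; z != z1; z += zs)
    for (int y = y0; y != y1; y += ys)
      for (int x = x0; x != x1; x += xs) {
        R_xlen_t v = (R_xlen_t)x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        double best = d[v];
        for (int k = 0; k < 13; ++k) {
          int xx = x + sgn * off[k][0];
          int yy = y + sgn * off[k][1];
          int zz = z + sgn * off[k][2];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
          R_xlen_t u = (R_xlen_t)xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
          double cand = d[u] + w[k];
          if (cand < best) best = cand;
        }
        d[v] = best;
      }
}

// Two-pass chamfer distance (voxel units) from the set of TRUE voxels.
static std::vector<double> chamfer_dist(const LogicalVector &mask, int nx,
                                        int ny, int nz) {
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double BIG = 1e30;
  std::vector<double> d(n);
  bool any = false;
  for (R_xlen_t i = 0; i < n; ++i) {
    d[i] = mask[i] ? 0.0 : BIG;
    if (mask[i]) any = true;
  }
  if (!any) return d;
  chamfer_pass(d, nx, ny, nz, true);
  chamfer_pass(d, nx, ny, nz, false);
  return d;
}

// Signed distance field: positive inside mask, negative outside, in voxel
// units (chamfer approximation). Object voxels get +distance-to-complement,
// background voxels -distance-to-object, so {phi >= 0} == mask exactly.
// [[Rcpp::export(name = ".cpp_signed_distance")]]
NumericVector cpp_signed_distance(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector inv(n);
  for (R_xlen_t i = 0; i < n; ++i) inv[i] = !mask[i];
  std::vector<double> din = chamfer_dist(inv, nx, ny, nz);   // dist to outside
  std::vector<double> dout = chamfer_dist(mask, nx, ny, nz); // dist to object
  NumericVector phi(n);
  phi.attr("dim") = dims;
  const double BIG = 1e29;
  for (R_xlen_t i = 0; i < n; ++i) {
    double a = din[i] > BIG ? (double)(nx + ny + nz) : din[i];
    double b = dout[i] > BIG ? (double)(nx + ny + nz) : dout[i];
    phi[i] = mask[i] ? a : -b;
  }
  return phi;
}
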