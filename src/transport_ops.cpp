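#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double BIG = 1e30;

// 1D lower envelope of parabolas (Felzenszwalb & Huttenlocher), abscissa step w.
static void dt1d(const std::vector<double>& f, double w,
                 std::vector<double>& d) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  const double w2 = w * w;
  for (int q = 1; q < n; ++q) {
    double s;
    int p = v[k];
    s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
    while (s <= z[k]) {
      --k;
      p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = w2 * (q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Exact squared Euclidean distance (mm^2) to the nearest feature voxel,
// anisotropic spacing, three separable passes.
// [[Rcpp::export(name = ".edt3_sq")]]
NumericVector edt3_sq(LogicalVector feature, IntegerVector dims,
                      NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = feature[i] ? 0.0 : BIG;

  std::vector<double> line, dl;
  // pass along x
  line.resize(nx); dl.resize(nx);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) line[i] = out[base + i];
      dt1d(line, spacing[0], dl);
      for (int i = 0; i < nx; ++i) out[base + i] = dl[i];
    }
  // pass along y
  line.resize(ny); dl.resize(ny);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * k;
      for (int j = 0; j < ny; ++j) line[j] = out[base + (R_xlen_t)nx * j];
      dt1d(line, spacing[1], dl);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)nx * j] = dl[j];
    }
  // pass along z
  line.resize(nz); dl.resize(nz);
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      for (int k = 0; k < nz; ++k) line[k] = out[base + sz * k];
      dt1d(line, spacing[2], dl);
      for (int k = 0; k < nz; ++k) out[base + sz * k] = dl[k];
    }
  return out;
}

// Connected components (6-connectivity) of voxels sharing the same positive
// label value. Returns component ids 1..C (0 for label <= 0).
// [[Rcpp::export(name = ".cc_labels")]]
IntegerVector cc_labels(IntegerVector lab, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector comp(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (lab[s] <= 0 || comp[s] != 0) continue;
    ++next;
    comp[s] = next;
    stack.clear();
    stack.push_back(s);
    const int lv = lab[s];
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      int i = (int)(p % nx), j = (int)((p / nx) % ny), k = (int)(p / sz);
      R_xlen_t nb[6];
      int nn = 0;
      if (i > 0) nb[nn++] = p - sx;
      if (i < nx - 1) nb[nn++] = p + sx;
      if (j > 0) nb[nn++] = p - sy;
      if (j < ny - 1) nb[nn++] = p + sy;
      if (k > 0) nb[nn++] = p - sz;
      if (k < nz - 1) nb[nn++] = p + sz;
      for (int q = 0; q < nn; ++q) {
        R_xlen_t t = nb[q];
        if (comp[t] == 0 && lab[t] == lv) {
          comp[t] = next;
          stack.push_back(t);
        }
      }
    }
  }
  return comp;
}

// Eigenvalues of symmetric 3x3 matrices (rows: xx, yy, zz, xy, xz, yz),
// returned sorted by increasing absolute value (Frangi ordering).
// [[Rcpp::export(name = ".eig3_sym")]]
NumericMatrix eig3_sym(NumericMatrix H) {
  const int n = H.nrow();
  NumericMatrix out(n, 3);
  for (int r = 0; r < n; ++r) {
    double a = H(r, 0), b = H(r, 1), c = H(r, 2);
    double d = H(r, 3), e = H(r, 4), f = H(r, 5);
    double p1 = d * d + e * e + f * f;
    double l1, l2, l3;
    if (p1 < 1e-300) {
      l1 = a; l2 = b; l3 = c;
    } else {
      double q = (a + b + c) / 3.0;
      double p2 = (a - q) * (a - q) + (b - q) * (b - q) + (c - q) * (c - q) +
                  2.0 * p1;
      double p = std::sqrt(p2 / 6.0);
      // B = (A - q I) / p ; r_ = det(B) / 2 in [-1, 1]
      double b11 = (a - q) / p, b22 = (b - q) / p, b33 = (c - q) / p;
      double b12 = d / p, b13 = e / p, b23 = f / p;
      double detB = b11 * (b22 * b33 - b23 * b23) -
                    b12 * (b12 * b33 - b23 * b13) +
                    b13 * (b12 * b23 - b22 * b13);
      double rr = detB / 2.0;
      if (rr < -1.0) rr = -1.0;
      if (rr > 1.0) rr = 1.0;
      double phi = std::acos(rr) / 3.0;
      l1 = q + 2.0 * p * std::cos(phi);
      l3 = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
      l2 = 3.0 * q - l1 - l3;
    }
    double v[3] = {l1, l2, l3};
    // sort by |lambda| ascending
    for (int i = 0; i < 2; ++i)
      for (int j = 0; j < 2 - i; ++j)
        if (std::fabs(v[j]) > std::fabs(v[j + 1])) {
          double t = v[j]; v[j] = v[j + 1]; v[j + 1] = t;
        }
    out(r, 0) = v[0];
    out(r, 1) = v[1];
    out(r, 2) = v[2];
  }
  return out;
}
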