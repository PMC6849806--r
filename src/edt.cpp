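#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// One-dimensional squared-distance transform (lower envelope of parabolas,
// Felzenszwalb & Huttenlocher), samples at coordinates j * step.  Entries
// with fin == Inf carry no parabola; if none is finite the line is left Inf.
static void dt1d(const std::vector<double> &fin, std::vector<double> &dout,
                 std::vector<int> &v, std::vector<double> &z,
                 int n, double step) {
  const double INF = std::numeric_limits<double>::infinity();
  int q0 = 0;
  while (q0 < n && fin[q0] == INF) ++q0;
  if (q0 == n) {
    for (int q = 0; q < n; ++q) dout[q] = INF;
    return;
  }
  int k = 0;
  v[0] = q0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = q0 + 1; q < n; ++q) {
    if (fin[q] == INF) continue;
    const double xq = q * step;
    double s;
    for (;;) {
      const int p = v[k];
      const double xp = p * step;
      s = ((fin[q] + xq * xq) - (fin[p] + xp * xp)) / (2.0 * (xq - xp));
      if (s <= z[k]) --k; else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    const double xq = q * step;
    while (z[k + 1] < xq) ++k;
    const double d = xq - v[k] * step;
    dout[q] = d * d + fin[v[k]];
  }
}

// Squared Euclidean distance (mm^2) from every voxel centre to the nearest
// voxel centre where `feature` is TRUE, with anisotropic spacing.
// If `feature` is empty everywhere the result is Inf everywhere.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector feature, IntegerVector dim,
                         NumericVector spacing) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const double INF = std::numeric_limits<double>::infinity();
  const R_xlen_t ntot = (R_xlen_t)n1 * n2 * n3;
  NumericVector out(ntot);
  for (R_xlen_t i = 0; i < ntot; ++i) out[i] = feature[i] ? 0.0 : INF;
  const int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // axis 1
  for (int c = 0; c < n3; ++c)
    for (int b = 0; b < n2; ++b) {
      const R_xlen_t base = (R_xlen_t)b * n1 + (R_xlen_t)c * n1 * n2;
      for (int a = 0; a < n1; ++a) f[a] = out[base + a];
      dt1d(f, d, v, z, n1, spacing[0]);
      for (int a = 0; a < n1; ++a) out[base + a] = d[a];
    }
  // axis 2
  for (int c = 0; c < n3; ++c)
    for (int a = 0; a < n1; ++a) {
      const R_xlen_t base = (R_xlen_t)a + (R_xlen_t)c * n1 * n2;
      for (int b = 0; b < n2; ++b) f[b] = out[base + (R_xlen_t)b * n1];
      dt1d(f, d, v, z, n2, spacing[1]);
      for (int b = 0; b < n2; ++b) out[base + (R_xlen_t)b * n1] = d[b];
    }
  // axis 3
  for (int b = 0; b < n2; ++b)
    for (int a = 0; a < n1; ++a) {
      const R_xlen_t base = (R_xlen_t)a + (R_xlen_t)b * n1;
      for (int c = 0; c < n3; ++c) f[c] = out[base + (R_xlen_t)c * n1 * n2];
      dt1d(f, d, v, z, n3, spacing[2]);
      for (int c = 0; c < n3; ++c) out[base + (R_xlen_t)c * n1 * n2] = d[c];
    }
  out.attr("dim") = dim;
  return out;
}
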