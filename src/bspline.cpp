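#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Cubic B-spline basis, support [-2, 2], partition of unity on integer shifts.
static inline double beta3(double t) {
  t = std::fabs(t);
  if (t < 1.0) return (4.0 - 6.0 * t * t + 3.0 * t * t * t) / 6.0;
  if (t < 2.0) { const double u = 2.0 - t; return u * u * u / 6.0; }
  return 0.0;
}

static inline double beta3_deriv(double t) {
  const double a = std::fabs(t), s = t < 0 ? -1.0 : 1.0;
  if (a < 1.0) return s * (-2.0 * a + 1.5 * a * a);
  if (a < 2.0) { const double u = 2.0 - a; return -s * 0.5 * u * u; }
  return 0.0;
}

// Displacement of a B-spline FFD at points given in 0-based lattice units
// u = (x - lattice_origin) / sigma.  coef has dim (nx, ny, nz, 3).
// Control points outside the lattice contribute zero (the R wrapper enforces
// the valid-support precondition u in [1, n-2]).
// [[Rcpp::export]]
NumericMatrix cpp_bspline_disp(NumericVector coef, IntegerVector cdim,
                               NumericMatrix u) {
  const int nx = cdim[0], ny = cdim[1], nz = cdim[2];
  const int n = u.nrow();
  const double *cf = coef.begin();
  const R_xlen_t stride = (R_xlen_t)nx * ny * nz;
  NumericMatrix out(n, 3);
  double wx[4], wy[4], wz[4];
  for (int i = 0; i < n; ++i) {
    const double ux = u(i, 0), uy = u(i, 1), uz = u(i, 2);
    const int ix = (int)std::floor(ux) - 1, iy = (int)std::floor(uy) - 1,
              iz = (int)std::floor(uz) - 1;
    for (int a = 0; a < 4; ++a) {
      wx[a] = beta3(ux - (ix + a));
      wy[a] = beta3(uy - (iy + a));
      wz[a] = beta3(uz - (iz + a));
    }
    double dx = 0.0, dy = 0.0, dz = 0.0;
    for (int c = 0; c < 4; ++c) {
      const int kz = iz + c;
      if (kz < 0 || kz >= nz) continue;
      for (int b = 0; b < 4; ++b) {
        const int ky = iy + b;
        if (ky < 0 || ky >= ny) continue;
        const double wyz = wy[b] * wz[c];
        const R_xlen_t base = (R_xlen_t)ky * nx + (R_xlen_t)kz * nx * ny;
        for (int a = 0; a < 4; ++a) {
          const int kx = ix + a;
          if (kx < 0 || kx >= nx) continue;
          const double w = wx[a] * wyz;
          const R_xlen_t off = base + kx;
          dx += w * cf[off];
          dy += w * cf[off + stride];
          dz += w * cf[off + 2 * stride];
        }
      }
    }
    out(i, 0) = dx; out(i, 1) = dy; out(i, 2) = dz;
  }
  return out;
}

// Accumulate sum_j w_k(u_j) * r_j into a coefficient-shaped gradient array:
// the chain-rule scatter of per-sample residual vectors r (n x 3) back to the
// B-spline coefficients.
// [[Rcpp::export]]
NumericVector cpp_bspline_scatter(IntegerVector cdim, NumericMatrix u,
                                  NumericMatrix r) {
  const int nx = cdim[0], ny = cdim[1], nz = cdim[2];
  const int n = u.nrow();
  const R_xlen_t stride = (R_xlen_t)nx * ny * nz;
  NumericVector grad(stride * 3);
  double *g = grad.begin();
  double wx[4], wy[4], wz[4];
  for (int i = 0; i < n; ++i) {
    const double rx = r(i, 0), ry = r(i, 1), rz = r(i, 2);
    if (!R_finite(rx) || !R_finite(ry) || !R_finite(rz)) continue;
    const double ux = u(i, 0), uy = u(i, 1), uz = u(i, 2);
    const int ix = (int)std::floor(ux) - 1, iy = (int)std::floor(uy) - 1,
              iz = (int)std::floor(uz) - 1;
    for (int a = 0; a < 4; ++a) {
      wx[a] = beta3(ux - (ix + a));
      wy[a] = beta3(uy - (iy + a));
      wz[a] = beta3(uz - (iz + a));
    }
    for (int c = 0; c < 4; ++c) {
      const int kz = iz + c;
      if (kz < 0 || kz >= nz) continue;
      for (int b = 0; b < 4; ++b) {
        const int ky = iy + b;
        if (ky < 0 || ky >= ny) continue;
        const double wyz = wy[b] * wz[c];
        const R_xlen_t base = (R_xlen_t)ky * nx + (R_xlen_t)kz * nx * ny;
        for (int a = 0; a < 4; ++a) {
          const int kx = ix + a;
          if (kx < 0 || kx >= nx) continue;
          const double w = wx[a] * wyz;
          const R_xlen_t off = base + kx;
          g[off] += w * rx;
          g[off + stride] += w * ry;
          g[off + 2 * stride] += w * rz;
        }
      }
    }
  }
  grad.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
  return grad;
}

// Tensor-product cubic B-spline weights needed by R-side code (exposed for
// testing the basis itself).
// [[Rcpp::export]]
NumericVector cpp_beta3(NumericVector t) {
  NumericVector out(t.size());
  for (R_xlen_t i = 0; i < t.size(); ++i) out[i] = beta3(t[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_beta3_deriv(NumericVector t) {
  NumericVector out(t.size());
  for (R_xlen_t i = 0; i < t.size(); ++i) out[i] = beta3_deriv(t[i]);
  return out;
}
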