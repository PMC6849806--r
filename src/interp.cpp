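#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear interpolation of a 3D volume at continuous 0-based voxel indices.
// Points outside [0, dim-1] on any axis receive `fill` (may be NA_REAL so the
// caller can detect and mask out-of-domain samples).
// [[Rcpp::export]]
NumericVector cpp_interp_trilinear(NumericVector vol, IntegerVector dim,
                                   NumericMatrix idx, double fill) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const int n = idx.nrow();
  const double *v = vol.begin();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double x = idx(i, 0), y = idx(i, 1), z = idx(i, 2);
    if (!R_finite(x) || !R_finite(y) || !R_finite(z) ||
        x < 0.0 || y < 0.0 || z < 0.0 ||
        x > n1 - 1.0 || y > n2 - 1.0 || z > n3 - 1.0) {
      out[i] = fill;
      continue;
    }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    if (x0 > n1 - 2) x0 = n1 > 1 ? n1 - 2 : 0;
    if (y0 > n2 - 2) y0 = n2 > 1 ? n2 - 2 : 0;
    if (z0 > n3 - 2) z0 = n3 > 1 ? n3 - 2 : 0;
    const double fx = x - x0, fy = y - y0, fz = z - z0;
    const int x1 = n1 > 1 ? x0 + 1 : x0;
    const int y1 = n2 > 1 ? y0 + 1 : y0;
    const int z1 = n3 > 1 ? z0 + 1 : z0;
    #define V(a, b, c) v[(a) + (b) * (R_xlen_t)n1 + (c) * (R_xlen_t)n1 * n2]
    const double c00 = V(x0, y0, z0) * (1 - fx) + V(x1, y0, z0) * fx;
    const double c10 = V(x0, y1, z0) * (1 - fx) + V(x1, y1, z0) * fx;
    const double c01 = V(x0, y0, z1) * (1 - fx) + V(x1, y0, z1) * fx;
    const double c11 = V(x0, y1, z1) * (1 - fx) + V(x1, y1, z1) * fx;
    #undef V
    const double c0 = c00 * (1 - fy) + c10 * fy;
    const double c1 = c01 * (1 - fy) + c11 * fy;
    out[i] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// Nearest-neighbour lookup at continuous 0-based voxel indices.
// [[Rcpp::export]]
NumericVector cpp_interp_nearest(NumericVector vol, IntegerVector dim,
                                 NumericMatrix idx, double fill) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const int n = idx.nrow();
  const double *v = vol.begin();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double x = idx(i, 0), y = idx(i, 1), z = idx(i, 2);
    if (!R_finite(x) || !R_finite(y) || !R_finite(z) ||
        x < -0.5 || y < -0.5 || z < -0.5 ||
        x > n1 - 0.5 || y > n2 - 0.5 || z > n3 - 0.5) {
      out[i] = fill;
      continue;
    }
    int xi = (int)std::floor(x + 0.5), yi = (int)std::floor(y + 0.5),
        zi = (int)std::floor(z + 0.5);
    if (xi < 0) xi = 0; if (xi > n1 - 1) xi = n1 - 1;
    if (yi < 0) yi = 0; if (yi > n2 - 1) yi = n2 - 1;
    if (zi < 0) zi = 0; if (zi > n3 - 1) zi = n3 - 1;
    out[i] = v[xi + yi * (R_xlen_t)n1 + zi * (R_xlen_t)n1 * n2];
  }
  return out;
}
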