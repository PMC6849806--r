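#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <map>
#include <array>
using namespace Rcpp;

// ---- Marching tetrahedra --------------------------------------------------
// Each grid cube is split into six tetrahedra around the main diagonal
// (corner 0 -> corner 6); per tetrahedron the iso-surface crossing has only
// single-triangle or quad cases, so no case table is required.  Vertices are
// emitted in physical mm coordinates and welded exactly (shared edges produce
// bitwise-identical interpolated points).

struct Weld {
  std::map<std::array<double, 3>, int> ix;
  std::vector<std::array<double, 3>> verts;
  int add(const std::array<double, 3> &p) {
    auto it = ix.find(p);
    if (it != ix.end()) return it->second;
    const int id = (int)verts.size();
    verts.push_back(p);
    ix[p] = id;
    return id;
  }
};

// corner offsets of a cube, binary (x, y, z)
static const int COFF[8][3] = {
  {0,0,0}, {1,0,0}, {1,1,0}, {0,1,0}, {0,0,1}, {1,0,1}, {1,1,1}, {0,1,1}
};
// six tetrahedra around diagonal 0-6
static const int TETS[6][4] = {
  {0,1,2,6}, {0,2,3,6}, {0,3,7,6}, {0,7,4,6}, {0,4,5,6}, {0,5,1,6}
};

static std::array<double, 3> edge_point(const double *pos, const double *val,
                                        int a, int b, double level) {
  double t;
  const double va = val[a], vb = val[b];
  if (va == vb) t = 0.5; else t = (level - va) / (vb - va);
  if (t < 0.0) t = 0.0;
  if (t > 1.0) t = 1.0;
  std::array<double, 3> p;
  for (int d = 0; d < 3; ++d)
    p[d] = pos[a * 3 + d] + t * (pos[b * 3 + d] - pos[a * 3 + d]);
  return p;
}

// [[Rcpp::export]]
List cpp_marching_tetrahedra(NumericVector vol, IntegerVector dim,
                             double level, NumericVector spacing,
                             NumericVector origin) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const double *v = vol.begin();
  Weld weld;
  std::vector<std::array<int, 3>> faces;
  double cpos[8 * 3], cval[8];
  for (int c = 0; c < n3 - 1; ++c)
    for (int b = 0; b < n2 - 1; ++b)
      for (int a = 0; a < n1 - 1; ++a) {
        bool below = false, above = false;
        for (int k = 0; k < 8; ++k) {
          const int x = a + COFF[k][0], y = b + COFF[k][1], z = c + COFF[k][2];
          cval[k] = v[x + (R_xlen_t)y * n1 + (R_xlen_t)z * n1 * n2];
          cpos[k * 3 + 0] = origin[0] + x * spacing[0];
          cpos[k * 3 + 1] = origin[1] + y * spacing[1];
          cpos[k * 3 + 2] = origin[2] + z * spacing[2];
          if (cval[k] < level) below = true; else above = true;
        }
        if (!below || !above) continue;
        for (int t = 0; t < 6; ++t) {
          const int *T = TETS[t];
          int in[4], nin = 0, out[4], nout = 0;
          for (int k = 0; k < 4; ++k) {
            if (cval[T[k]] < level) in[nin++] = T[k]; else out[nout++] = T[k];
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1 || nin == 3) {
            const int apex = nin == 1 ? in[0] : out[0];
            const int *rest = nin == 1 ? out : in;
            const int i0 = weld.add(edge_point(cpos, cval, apex, rest[0], level));
            const int i1 = weld.add(edge_point(cpos, cval, apex, rest[1], level));
            const int i2 = weld.add(edge_point(cpos, cval, apex, rest[2], level));
            if (i0 != i1 && i1 != i2 && i0 != i2)
              faces.push_back({i0, i1, i2});
          } else {
            // 2-2 split: quad with corners on edges in0-out0, in0-out1,
            // in1-out1, in1-out0
            const int q0 = weld.add(edge_point(cpos, cval, in[0], out[0], level));
            const int q1 = weld.add(edge_point(cpos, cval, in[0], out[1], level));
            const int q2 = weld.add(edge_point(cpos, cval, in[1], out[1], level));
            const int q3 = weld.add(edge_point(cpos, cval, in[1], out[0], level));
            if (q0 != q1 && q1 != q2 && q0 != q2)
              faces.push_back({q0, q1, q2});
            if (q0 != q2 && q2 != q3 && q0 != q3)
              faces.push_back({q0, q2, q3});
          }
        }
      }
  NumericMatrix V((int)weld.verts.size(), 3);
  for (int i = 0; i < (int)weld.verts.size(); ++i)
    for (int d = 0; d < 3; ++d) V(i, d) = weld.verts[i][d];
  IntegerMatrix F((int)faces.size(), 3);
  for (int i = 0; i < (int)faces.size(); ++i)
    for (int d = 0; d < 3; ++d) F(i, d) = faces[i][d] + 1;  // 1-based
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// ---- Exact point-to-triangle distance -------------------------------------
// Closest point on triangle (Ericson, Real-Time Collision Detection).
static double pt_tri_sq(const double *p, const double *a, const double *b,
                        const double *c) {
  double ab[3], ac[3], ap[3];
  for (int d = 0; d < 3; ++d) {
    ab[d] = b[d] - a[d];
    ac[d] = c[d] - a[d];
    ap[d] = p[d] - a[d];
  }
  auto dot = [](const double *x, const double *y) {
    return x[0] * y[0] + x[1] * y[1] + x[2] * y[2];
  };
  auto sqd = [&](const double *q) {
    double dx = p[0] - q[0], dy = p[1] - q[1], dz = p[2] - q[2];
    return dx * dx + dy * dy + dz * dz;
  };
  const double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return sqd(a);
  double bp[3] = {p[0] - b[0], p[1] - b[1], p[2] - b[2]};
  const double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return sqd(b);
  const double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    const double t = d1 / (d1 - d3);
    double q[3] = {a[0] + t * ab[0], a[1] + t * ab[1], a[2] + t * ab[2]};
    return sqd(q);
  }
  double cp[3] = {p[0] - c[0], p[1] - c[1], p[2] - c[2]};
  const double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return sqd(c);
  const double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    const double t = d2 / (d2 - d6);
    double q[3] = {a[0] + t * ac[0], a[1] + t * ac[1], a[2] + t * ac[2]};
    return sqd(q);
  }
  const double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    const double t = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    double q[3] = {b[0] + t * (c[0] - b[0]), b[1] + t * (c[1] - b[1]),
                   b[2] + t * (c[2] - b[2])};
    return sqd(q);
  }
  const double denom = 1.0 / (va + vb + vc);
  const double vv = vb * denom, ww = vc * denom;
  double q[3] = {a[0] + ab[0] * vv + ac[0] * ww, a[1] + ab[1] * vv + ac[1] * ww,
                 a[2] + ab[2] * vv + ac[2] * ww};
  return sqd(q);
}

// Exact min distance from each point to a triangle mesh (faces 1-based).
// [[Rcpp::export]]
NumericVector cpp_point_mesh_dist(NumericMatrix pts, NumericMatrix verts,
                                  IntegerMatrix faces) {
  const int np = pts.nrow(), nf = faces.nrow();
  NumericVector out(np);
  std::vector<double> P(np * 3), V(verts.nrow() * 3);
  for (int i = 0; i < np; ++i)
    for (int d = 0; d < 3; ++d) P[i * 3 + d] = pts(i, d);
  for (int i = 0; i < verts.nrow(); ++i)
    for (int d = 0; d < 3; ++d) V[i * 3 + d] = verts(i, d);
  // precompute face vertex pointers and centroids for a cheap lower bound
  std::vector<int> fa(nf), fb(nf), fc(nf);
  std::vector<double> cx(nf), cy(nf), cz(nf), rad(nf);
  for (int f = 0; f < nf; ++f) {
    fa[f] = faces(f, 0) - 1; fb[f] = faces(f, 1) - 1; fc[f] = faces(f, 2) - 1;
    const double *a = &V[fa[f] * 3], *b = &V[fb[f] * 3], *c = &V[fc[f] * 3];
    cx[f] = (a[0] + b[0] + c[0]) / 3.0;
    cy[f] = (a[1] + b[1] + c[1]) / 3.0;
    cz[f] = (a[2] + b[2] + c[2]) / 3.0;
    double r2 = 0.0;
    for (const double *q : {a, b, c}) {
      const double dx = q[0] - cx[f], dy = q[1] - cy[f], dz = q[2] - cz[f];
      const double r = dx * dx + dy * dy + dz * dz;
      if (r > r2) r2 = r;
    }
    rad[f] = std::sqrt(r2);
  }
  for (int i = 0; i < np; ++i) {
    const double *p = &P[i * 3];
    double best = R_PosInf, bestd = R_PosInf;  // bestd = sqrt(best)
    for (int f = 0; f < nf; ++f) {
      const double dx = p[0] - cx[f], dy = p[1] - cy[f], dz = p[2] - cz[f];
      const double dc = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (dc - rad[f] >= bestd) continue;  // cannot beat current best
      const double d2 = pt_tri_sq(p, &V[fa[f] * 3], &V[fb[f] * 3], &V[fc[f] * 3]);
      if (d2 < best) { best = d2; bestd = std::sqrt(best); }
    }
    out[i] = bestd;
  }
  return out;
}
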