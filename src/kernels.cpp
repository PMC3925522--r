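// Geometric kernels: ray/segment-triangle intersection (Moller-Trumbore),
// closest point on triangle (Ericson), banded unsigned distance fields,
// marching-tetrahedra iso-surfacing, and tolerance welding.
// All coordinates are millimetres.

#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cmath>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 v3(double x, double y, double z) { return Vec3{x, y, z}; }
inline Vec3 operator-(const Vec3& a, const Vec3& b) {
  return v3(a.x - b.x, a.y - b.y, a.z - b.z);
}
inline Vec3 operator+(const Vec3& a, const Vec3& b) {
  return v3(a.x + b.x, a.y + b.y, a.z + b.z);
}
inline Vec3 operator*(const Vec3& a, double s) {
  return v3(a.x * s, a.y * s, a.z * s);
}
inline double dot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return v3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
            a.x * b.y - a.y * b.x);
}
inline double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }

inline Vec3 vrow(const NumericMatrix& M, int i) {
  return v3(M(i, 0), M(i, 1), M(i, 2));
}

// Moller-Trumbore. Returns t along (origin, dir) or a negative value on miss.
// u, v barycentric outputs are unused by callers but kept for clarity.
inline double ray_tri(const Vec3& o, const Vec3& d, const Vec3& a,
                      const Vec3& b, const Vec3& c) {
  const Vec3 e1 = b - a;
  const Vec3 e2 = c - a;
  const Vec3 p = cross(d, e2);
  const double det = dot(e1, p);
  if (std::fabs(det) < 1e-14) return -1.0;
  const double inv = 1.0 / det;
  const Vec3 tv = o - a;
  const double u = dot(tv, p) * inv;
  if (u < -1e-12 || u > 1.0 + 1e-12) return -1.0;
  const Vec3 q = cross(tv, e1);
  const double v = dot(d, q) * inv;
  if (v < -1e-12 || u + v > 1.0 + 1e-12) return -1.0;
  return dot(e2, q) * inv;
}

// Ericson, Real-Time Collision Detection, closest point on triangle.
inline Vec3 closest_on_tri(const Vec3& p, const Vec3& a, const Vec3& b,
                           const Vec3& c) {
  const Vec3 ab = b - a, ac = c - a, ap = p - a;
  const double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return a;
  const Vec3 bp = p - b;
  const double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return b;
  const double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    const double v = d1 / (d1 - d3);
    return a + ab * v;
  }
  const Vec3 cp = p - c;
  const double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return c;
  const double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    const double w = d2 / (d2 - d6);
    return a + ac * w;
  }
  const double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    const double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return b + (c - b) * w;
  }
  const double denom = 1.0 / (va + vb + vc);
  const double v = vb * denom, w = vc * denom;
  return a + ab * v + ac * w;
}

// Uniform-grid acceleration structure over triangle bounding boxes.
struct TriGrid {
  Vec3 lo, hi;
  double cell[3];
  int n[3];
  std::vector<std::vector<int>> cells;

  int idx(int i, int j, int k) const { return (k * n[1] + j) * n[0] + i; }

  void build(const NumericMatrix& V, const IntegerMatrix& F) {
    const int nf = F.nrow();
    lo = v3(R_PosInf, R_PosInf, R_PosInf);
    hi = v3(R_NegInf, R_NegInf, R_NegInf);
    for (int i = 0; i < V.nrow(); ++i) {
      lo.x = std::min(lo.x, V(i, 0));
      lo.y = std::min(lo.y, V(i, 1));
      lo.z = std::min(lo.z, V(i, 2));
      hi.x = std::max(hi.x, V(i, 0));
      hi.y = std::max(hi.y, V(i, 1));
      hi.z = std::max(hi.z, V(i, 2));
    }
    const double pad = 1e-6 + 1e-9 * (norm(hi - lo) + 1.0);
    lo = lo - v3(pad, pad, pad);
    hi = hi + v3(pad, pad, pad);
    const double ex = hi.x - lo.x, ey = hi.y - lo.y, ez = hi.z - lo.z;
    const double vol = std::max(ex * ey * ez, 1e-12);
    const double target = std::cbrt(2.0 * std::max(nf, 1) / vol);
    n[0] = std::max(1, std::min(256, (int)std::ceil(ex * target)));
    n[1] = std::max(1, std::min(256, (int)std::ceil(ey * target)));
    n[2] = std::max(1, std::min(256, (int)std::ceil(ez * target)));
    cell[0] = ex / n[0];
    cell[1] = ey / n[1];
    cell[2] = ez / n[2];
    cells.assign((size_t)n[0] * n[1] * n[2], {});
    for (int f = 0; f < nf; ++f) {
      const Vec3 a = vrow(V, F(f, 0) - 1), b = vrow(V, F(f, 1) - 1),
                 c = vrow(V, F(f, 2) - 1);
      double blo[3] = {std::min({a.x, b.x, c.x}), std::min({a.y, b.y, c.y}),
                       std::min({a.z, b.z, c.z})};
      double bhi[3] = {std::max({a.x, b.x, c.x}), std::max({a.y, b.y, c.y}),
                       std::max({a.z, b.z, c.z})};
      int ilo[3], ihi[3];
      const double l[3] = {lo.x, lo.y, lo.z};
      for (int ax = 0; ax < 3; ++ax) {
        ilo[ax] = std::max(
            0, std::min(n[ax] - 1,
                        (int)std::floor((blo[ax] - 1e-9 - l[ax]) / cell[ax])));
        ihi[ax] = std::max(
            0, std::min(n[ax] - 1,
                        (int)std::floor((bhi[ax] + 1e-9 - l[ax]) / cell[ax])));
      }
      for (int k = ilo[2]; k <= ihi[2]; ++k)
        for (int j = ilo[1]; j <= ihi[1]; ++j)
          for (int i = ilo[0]; i <= ihi[0]; ++i)
            cells[idx(i, j, k)].push_back(f);
    }
  }
};

// Does the open segment (o, o + d), param in (tmin, tmax) of |d| = 1 param
// units, hit any triangle? Brute force.
inline bool seg_any_hit_brute(const NumericMatrix& V, const IntegerMatrix& F,
                              const Vec3& o, const Vec3& d, double tmin,
                              double tmax) {
  const int nf = F.nrow();
  for (int f = 0; f < nf; ++f) {
    const double t = ray_tri(o, d, vrow(V, F(f, 0) - 1), vrow(V, F(f, 1) - 1),
                             vrow(V, F(f, 2) - 1));
    if (t > tmin && t < tmax) return true;
  }
  return false;
}

// Grid-accelerated any-hit with 3-DDA traversal. Exactness relies on
// conservative bbox binning; traversal bounds carry a small slack so a
// triangle straddling a cell wall is still reached before early exit.
inline bool seg_any_hit_grid(const NumericMatrix& V, const IntegerMatrix& F,
                             const TriGrid& g, std::vector<int>& stamp,
                             int qid, const Vec3& o, const Vec3& d,
                             double tmin, double tmax) {
  // Clip segment parameter range to the grid box.
  double t0 = 0.0, t1 = tmax;
  const double l[3] = {g.lo.x, g.lo.y, g.lo.z};
  const double h[3] = {g.hi.x, g.hi.y, g.hi.z};
  const double oo[3] = {o.x, o.y, o.z};
  const double dd[3] = {d.x, d.y, d.z};
  for (int ax = 0; ax < 3; ++ax) {
    if (std::fabs(dd[ax]) < 1e-300) {
      if (oo[ax] < l[ax] || oo[ax] > h[ax]) return false;
    } else {
      double ta = (l[ax] - oo[ax]) / dd[ax];
      double tb = (h[ax] - oo[ax]) / dd[ax];
      if (ta > tb) std::swap(ta, tb);
      t0 = std::max(t0, ta);
      t1 = std::min(t1, tb);
    }
  }
  if (t0 > t1) return false;
  const double slack = 1e-9 * std::max(1.0, t1);
  // Entry cell.
  const Vec3 entry = o + d * std::max(0.0, t0);
  int ci[3];
  double tnext[3], tdelta[3];
  int step[3];
  const double e[3] = {entry.x, entry.y, entry.z};
  for (int ax = 0; ax < 3; ++ax) {
    ci[ax] = std::max(
        0, std::min(g.n[ax] - 1, (int)std::floor((e[ax] - l[ax]) / g.cell[ax])));
    if (dd[ax] > 0) {
      step[ax] = 1;
      tnext[ax] = (l[ax] + (ci[ax] + 1) * g.cell[ax] - oo[ax]) / dd[ax];
      tdelta[ax] = g.cell[ax] / dd[ax];
    } else if (dd[ax] < 0) {
      step[ax] = -1;
      tnext[ax] = (l[ax] + ci[ax] * g.cell[ax] - oo[ax]) / dd[ax];
      tdelta[ax] = -g.cell[ax] / dd[ax];
    } else {
      step[ax] = 0;
      tnext[ax] = R_PosInf;
      tdelta[ax] = R_PosInf;
    }
  }
  while (true) {
    const std::vector<int>& cl = g.cells[g.idx(ci[0], ci[1], ci[2])];
    for (size_t m = 0; m < cl.size(); ++m) {
      const int f = cl[m];
      if (stamp[f] == qid) continue;
      stamp[f] = qid;
      const double t = ray_tri(o, d, vrow(V, F(f, 0) - 1), vrow(V, F(f, 1) - 1),
                               vrow(V, F(f, 2) - 1));
      if (t > tmin && t < tmax) return true;
    }
    int ax = 0;
    if (tnext[1] < tnext[ax]) ax = 1;
    if (tnext[2] < tnext[ax]) ax = 2;
    if (tnext[ax] > t1 + slack) return false;
    ci[ax] += step[ax];
    if (ci[ax] < 0 || ci[ax] >= g.n[ax]) return false;
    tnext[ax] += tdelta[ax];
  }
}

}  // namespace

namespace {

// Owns mesh copies plus the acceleration grid so repeated occlusion
// queries (landmark refinement) do not rebuild the structure.
struct MeshAccel {
  NumericMatrix V;
  IntegerMatrix F;
  TriGrid grid;
  std::vector<int> stamp;
  int qid = 0;
  bool use_grid = false;
};

}  // namespace

// Build a reusable occlusion accelerator for a mesh.
// [[Rcpp::export]]
SEXP cpp_mesh_accel(NumericMatrix V, IntegerMatrix F, int accel_min_faces) {
  XPtr<MeshAccel> p(new MeshAccel(), true);
  p->V = V;
  p->F = F;
  p->use_grid = F.nrow() >= accel_min_faces;
  if (p->use_grid) {
    p->grid.build(V, F);
    p->stamp.assign(F.nrow(), -1);
  }
  return p;
}

// Occlusion matrix against a prebuilt accelerator; same semantics as
// cpp_occlusion_matrix. early_exit_all: stop scanning viewpoints for a
// point once one viewpoint is clear (used for all-viewpoints predicates;
// remaining entries are left NA).
// [[Rcpp::export]]
LogicalMatrix cpp_occlusion_matrix_accel(SEXP accel, NumericMatrix points,
                                         NumericMatrix viewpoints,
                                         double eps_len, bool early_exit_all) {
  XPtr<MeshAccel> p(accel);
  const int np = points.nrow(), nv = viewpoints.nrow();
  LogicalMatrix out(np, nv);
  for (int i = 0; i < np; ++i) {
    const Vec3 pt = vrow(points, i);
    for (int j = 0; j < nv; ++j) {
      const Vec3 vp = vrow(viewpoints, j);
      const Vec3 d = pt - vp;
      const double L = norm(d);
      if (L < eps_len) {
        out(i, j) = NA_LOGICAL;
        continue;
      }
      const double tmin = eps_len / L, tmax = 1.0 - eps_len / L;
      bool hit;
      if (p->use_grid) {
        hit = seg_any_hit_grid(p->V, p->F, p->grid, p->stamp, p->qid++, vp, d,
                               tmin, tmax);
      } else {
        hit = seg_any_hit_brute(p->V, p->F, vp, d, tmin, tmax);
      }
      out(i, j) = hit;
      if (early_exit_all && !hit) {
        for (int jj = j + 1; jj < nv; ++jj) out(i, jj) = NA_LOGICAL;
        break;
      }
    }
  }
  return out;
}

// All intersections of one ray with a mesh, brute force over triangles.
// Hits with t <= eps or t > max_t are discarded; result is unsorted
// (sorted on the R side).
// [[Rcpp::export]]
List cpp_ray_hits(NumericMatrix V, IntegerMatrix F, NumericVector origin,
                  NumericVector dir, double max_t, double eps) {
  const Vec3 o = v3(origin[0], origin[1], origin[2]);
  const Vec3 d = v3(dir[0], dir[1], dir[2]);
  std::vector<double> ts;
  std::vector<int> faces;
  const int nf = F.nrow();
  for (int f = 0; f < nf; ++f) {
    const double t = ray_tri(o, d, vrow(V, F(f, 0) - 1), vrow(V, F(f, 1) - 1),
                             vrow(V, F(f, 2) - 1));
    if (t > eps && t <= max_t) {
      ts.push_back(t);
      faces.push_back(f + 1);
    }
  }
  return List::create(_["t"] = ts, _["face"] = faces);
}

// Count intersections of many rays (parity-style inside/outside testing).
// [[Rcpp::export]]
IntegerVector cpp_ray_hit_counts(NumericMatrix V, IntegerMatrix F,
                                 NumericMatrix origins, NumericMatrix dirs,
                                 double eps) {
  const int nr = origins.nrow(), nf = F.nrow();
  IntegerVector out(nr);
  for (int r = 0; r < nr; ++r) {
    const Vec3 o = vrow(origins, r);
    const Vec3 d = vrow(dirs, r);
    int cnt = 0;
    for (int f = 0; f < nf; ++f) {
      const double t = ray_tri(o, d, vrow(V, F(f, 0) - 1), vrow(V, F(f, 1) - 1),
                               vrow(V, F(f, 2) - 1));
      if (t > eps) ++cnt;
    }
    out[r] = cnt;
  }
  return out;
}

// Occlusion matrix: entry (i, j) is TRUE when the open segment from
// viewpoint j to point i intersects the occluder mesh. eps_len is an
// absolute clip (mm) at both segment ends. A uniform grid accelerator is
// used above `accel_min_faces` faces, plain scanning below.
// [[Rcpp::export]]
LogicalMatrix cpp_occlusion_matrix(NumericMatrix V, IntegerMatrix F,
                                   NumericMatrix points,
                                   NumericMatrix viewpoints, double eps_len,
                                   int accel_min_faces) {
  const int np = points.nrow(), nv = viewpoints.nrow(), nf = F.nrow();
  LogicalMatrix out(np, nv);
  const bool use_grid = nf >= accel_min_faces;
  TriGrid grid;
  std::vector<int> stamp;
  if (use_grid) {
    grid.build(V, F);
    stamp.assign(nf, -1);
  }
  int qid = 0;
  for (int j = 0; j < nv; ++j) {
    const Vec3 vp = vrow(viewpoints, j);
    for (int i = 0; i < np; ++i) {
      const Vec3 p = vrow(points, i);
      const Vec3 d = p - vp;
      const double L = norm(d);
      if (L < eps_len) {
        out(i, j) = NA_LOGICAL;
        continue;
      }
      const double tmin = eps_len / L, tmax = 1.0 - eps_len / L;
      bool hit;
      if (use_grid) {
        hit = seg_any_hit_grid(V, F, grid, stamp, qid++, vp, d, tmin, tmax);
      } else {
        hit = seg_any_hit_brute(V, F, vp, d, tmin, tmax);
      }
      out(i, j) = hit;
    }
  }
  return out;
}

// Unsigned distance and nearest face index for each query point.
// [[Rcpp::export]]
List cpp_point_mesh_distance(NumericMatrix V, IntegerMatrix F,
                             NumericMatrix points) {
  const int np = points.nrow(), nf = F.nrow();
  NumericVector dist(np);
  IntegerVector face(np);
  NumericMatrix nearest(np, 3);
  for (int i = 0; i < np; ++i) {
    const Vec3 p = vrow(points, i);
    double best = R_PosInf;
    int bf = -1;
    Vec3 bq = p;
    for (int f = 0; f < nf; ++f) {
      const Vec3 q = closest_on_tri(p, vrow(V, F(f, 0) - 1), vrow(V, F(f, 1) - 1),
                                    vrow(V, F(f, 2) - 1));
      const Vec3 w = p - q;
      const double d2 = dot(w, w);
      if (d2 < best) {
        best = d2;
        bf = f;
        bq = q;
      }
    }
    dist[i] = std::sqrt(best);
    face[i] = bf + 1;
    nearest(i, 0) = bq.x;
    nearest(i, 1) = bq.y;
    nearest(i, 2) = bq.z;
  }
  return List::create(_["distance"] = dist, _["face"] = face,
                      _["nearest"] = nearest);
}

// Banded unsigned distance field on a regular grid (x fastest). Voxels
// farther than `band` from every triangle keep a large sentinel value;
// the band must exceed the iso level plus a few voxel diagonals so that
// every voxel adjacent to the iso surface holds its exact distance.
// [[Rcpp::export]]
NumericVector cpp_distance_field_band(NumericMatrix V, IntegerMatrix F,
                                      NumericVector origin, double pitch,
                                      IntegerVector dims, double band) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  NumericVector field((R_xlen_t)nx * ny * nz, 1e30);
  double* fp = REAL(field);
  const int nf = F.nrow();
  for (int f = 0; f < nf; ++f) {
    const Vec3 a = vrow(V, F(f, 0) - 1), b = vrow(V, F(f, 1) - 1), c = vrow(V, F(f, 2) - 1);
    const double blo[3] = {std::min({a.x, b.x, c.x}) - band,
                           std::min({a.y, b.y, c.y}) - band,
                           std::min({a.z, b.z, c.z}) - band};
    const double bhi[3] = {std::max({a.x, b.x, c.x}) + band,
                           std::max({a.y, b.y, c.y}) + band,
                           std::max({a.z, b.z, c.z}) + band};
    const int i0 = std::max(0, (int)std::ceil((blo[0] - ox) / pitch));
    const int i1 = std::min(nx - 1, (int)std::floor((bhi[0] - ox) / pitch));
    const int j0 = std::max(0, (int)std::ceil((blo[1] - oy) / pitch));
    const int j1 = std::min(ny - 1, (int)std::floor((bhi[1] - oy) / pitch));
    const int k0 = std::max(0, (int)std::ceil((blo[2] - oz) / pitch));
    const int k1 = std::min(nz - 1, (int)std::floor((bhi[2] - oz) / pitch));
    for (int k = k0; k <= k1; ++k) {
      const double pz = oz + k * pitch;
      for (int j = j0; j <= j1; ++j) {
        const double py = oy + j * pitch;
        R_xlen_t base = ((R_xlen_t)k * ny + j) * nx;
        for (int i = i0; i <= i1; ++i) {
          const Vec3 p = v3(ox + i * pitch, py, pz);
          const Vec3 q = closest_on_tri(p, a, b, c);
          const Vec3 w = p - q;
          const double d2 = dot(w, w);
          if (d2 < fp[base + i]) fp[base + i] = d2;
        }
      }
    }
  }
  for (R_xlen_t i = 0; i < field.size(); ++i)
    fp[i] = (fp[i] >= 1e29) ? 1e30 : std::sqrt(fp[i]);
  return field;
}

namespace {

// Cube corner offsets, bit order x = 1, y = 2, z = 4.
const int kCorner[8][3] = {{0, 0, 0}, {1, 0, 0}, {0, 1, 0}, {1, 1, 0},
                           {0, 0, 1}, {1, 0, 1}, {0, 1, 1}, {1, 1, 1}};
// Six tetrahedra sharing the 0-7 diagonal.
const int kTet[6][4] = {{0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
                        {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}};

struct MTBuilder {
  std::unordered_map<long long, int> edge_vertex;
  std::vector<double> verts;  // x, y, z triples
  std::vector<int> tris;      // 0-based vertex ids

  long long n_nodes = 0;  // total grid nodes, set before use

  // Vertex on the grid edge between global node ids na < nb, interpolated.
  // The (na, nb) pair is encoded exactly: na * (n_nodes + 1) + nb stays
  // well below 2^63 for any grid that fits in memory.
  int edge_vert(long long na, long long nb, double va, double vb,
                const double* pa, const double* pb, double level) {
    if (na > nb) {
      std::swap(na, nb);
      std::swap(va, vb);
      const double* tmp = pa;
      pa = pb;
      pb = tmp;
    }
    const long long key = na * (n_nodes + 1) + nb;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    const double s = (level - va) / (vb - va);
    const int id = (int)(verts.size() / 3);
    verts.push_back(pa[0] + s * (pb[0] - pa[0]));
    verts.push_back(pa[1] + s * (pb[1] - pa[1]));
    verts.push_back(pa[2] + s * (pb[2] - pa[2]));
    edge_vertex.emplace(key, id);
    return id;
  }
};

}  // namespace

// Marching tetrahedra: extract the iso-surface field == level. Vertices on
// shared grid edges are merged exactly via edge keys, so the output of a
// closed iso-surface is watertight. Triangle orientation is not normalised.
// [[Rcpp::export]]
List cpp_marching_tets(NumericVector field, IntegerVector dims,
                       NumericVector origin, double pitch, double level) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double* fp = REAL(field);
  MTBuilder mb;
  mb.n_nodes = (long long)nx * ny * nz;
  double pos[8][3];
  double val[8];
  long long nid[8];
  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      for (int i = 0; i + 1 < nx; ++i) {
        bool lo = false, hi = false;
        for (int c = 0; c < 8; ++c) {
          const int ci = i + kCorner[c][0], cj = j + kCorner[c][1],
                    ck = k + kCorner[c][2];
          nid[c] = ((long long)ck * ny + cj) * nx + ci;
          double v = fp[nid[c]];
          if (v == level) v = level + 1e-12 * (std::fabs(level) + 1.0);
          val[c] = v;
          pos[c][0] = origin[0] + ci * pitch;
          pos[c][1] = origin[1] + cj * pitch;
          pos[c][2] = origin[2] + ck * pitch;
          if (v < level) lo = true; else hi = true;
        }
        if (!lo || !hi) continue;
        for (int t = 0; t < 6; ++t) {
          const int* T = kTet[t];
          int neg[4], pos_i[4];
          int nn = 0, np = 0;
          for (int m = 0; m < 4; ++m) {
            if (val[T[m]] < level) neg[nn++] = T[m];
            else pos_i[np++] = T[m];
          }
          if (nn == 0 || nn == 4) continue;
          if (nn == 1 || nn == 3) {
            const int apex = (nn == 1) ? neg[0] : pos_i[0];
            const int* others = (nn == 1) ? pos_i : neg;
            int e[3];
            for (int m = 0; m < 3; ++m)
              e[m] = mb.edge_vert(nid[apex], nid[others[m]], val[apex],
                                  val[others[m]], pos[apex], pos[others[m]],
                                  level);
            if (e[0] != e[1] && e[1] != e[2] && e[0] != e[2]) {
              mb.tris.push_back(e[0]);
              mb.tris.push_back(e[1]);
              mb.tris.push_back(e[2]);
            }
          } else {
            // Two-two split: quad spanned by the four crossing edges.
            const int a0 = neg[0], a1 = neg[1], b0 = pos_i[0], b1 = pos_i[1];
            const int e00 = mb.edge_vert(nid[a0], nid[b0], val[a0], val[b0],
                                         pos[a0], pos[b0], level);
            const int e01 = mb.edge_vert(nid[a0], nid[b1], val[a0], val[b1],
                                         pos[a0], pos[b1], level);
            const int e10 = mb.edge_vert(nid[a1], nid[b0], val[a1], val[b0],
                                         pos[a1], pos[b0], level);
            const int e11 = mb.edge_vert(nid[a1], nid[b1], val[a1], val[b1],
                                         pos[a1], pos[b1], level);
            if (e00 != e01 && e01 != e10 && e00 != e10) {
              mb.tris.push_back(e00);
              mb.tris.push_back(e01);
              mb.tris.push_back(e10);
            }
            if (e01 != e11 && e11 != e10 && e01 != e10) {
              mb.tris.push_back(e01);
              mb.tris.push_back(e11);
              mb.tris.push_back(e10);
            }
          }
        }
      }
    }
  }
  const int nv = (int)(mb.verts.size() / 3);
  NumericMatrix Vout(nv, 3);
  for (int i = 0; i < nv; ++i) {
    Vout(i, 0) = mb.verts[3 * i];
    Vout(i, 1) = mb.verts[3 * i + 1];
    Vout(i, 2) = mb.verts[3 * i + 2];
  }
  const int nt = (int)(mb.tris.size() / 3);
  IntegerMatrix Fout(nt, 3);
  for (int i = 0; i < nt; ++i) {
    Fout(i, 0) = mb.tris[3 * i] + 1;
    Fout(i, 1) = mb.tris[3 * i + 1] + 1;
    Fout(i, 2) = mb.tris[3 * i + 2] + 1;
  }
  return List::create(_["vertices"] = Vout, _["faces"] = Fout);
}

// Weld vertices within `tol` by snapping to a tolerance lattice.
// Returns the 1-based mapping old index -> new index plus merged vertices
// (coordinates of the first occurrence are kept).
// [[Rcpp::export]]
List cpp_weld(NumericMatrix V, double tol) {
  struct KeyHash {
    size_t operator()(const std::array<long long, 3>& k) const {
      size_t h = 1469598103934665603ULL;
      for (long long v : k) {
        h ^= (size_t)v;
        h *= 1099511628211ULL;
      }
      return h;
    }
  };
  const int n = V.nrow();
  std::unordered_map<std::array<long long, 3>, int, KeyHash> seen;
  seen.reserve((size_t)n * 2);
  IntegerVector map(n);
  std::vector<double> kept;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    const std::array<long long, 3> key = {
        (long long)std::llround(V(i, 0) / tol),
        (long long)std::llround(V(i, 1) / tol),
        (long long)std::llround(V(i, 2) / tol)};
    auto it = seen.find(key);
    if (it == seen.end()) {
      seen.emplace(key, next);
      kept.push_back(V(i, 0));
      kept.push_back(V(i, 1));
      kept.push_back(V(i, 2));
      map[i] = ++next;  // 1-based
    } else {
      map[i] = it->second + 1;
    }
  }
  NumericMatrix Vout(next, 3);
  for (int i = 0; i < next; ++i) {
    Vout(i, 0) = kept[3 * i];
    Vout(i, 1) = kept[3 * i + 1];
    Vout(i, 2) = kept[3 * i + 2];
  }
  return List::create(_["map"] = map, _["vertices"] = Vout);
}
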