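// Geometry kernels: point-to-triangle distance queries, ray casting,
// marching-tetrahedra isosurface extraction, parity voxelization and
// greedy Poisson-disk selection.  All coordinates in mm, indices 0-based
// at this layer (R wrappers convert).
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
#include <functional>

using namespace Rcpp;

namespace {

struct V3 {
  double x, y, z;
};
inline V3 v3(double x, double y, double z) { return V3{x, y, z}; }
inline V3 operator-(const V3& a, const V3& b) { return v3(a.x - b.x, a.y - b.y, a.z - b.z); }
inline V3 operator+(const V3& a, const V3& b) { return v3(a.x + b.x, a.y + b.y, a.z + b.z); }
inline V3 operator*(double s, const V3& a) { return v3(s * a.x, s * a.y, s * a.z); }
inline double dot(const V3& a, const V3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline V3 cross(const V3& a, const V3& b) {
  return v3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
inline double norm2(const V3& a) { return dot(a, a); }

// Closest point on triangle (Eberly's region decomposition).
V3 closest_on_triangle(const V3& p, const V3& a, const V3& b, const V3& c) {
  V3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return a;
  V3 bp = p - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    return a + v * ab;
  }
  V3 cp = p - c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    return a + w * ac;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return b + w * (c - b);
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return a + v * ab + w * ac;
}

}  // namespace

// [[Rcpp::export]]
List cpp_closest_on_mesh(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  const int np = P.nrow(), nf = F.nrow();
  if (nf == 0) stop("mesh has no faces");
  std::vector<V3> verts(V.nrow());
  for (int i = 0; i < V.nrow(); ++i) verts[i] = v3(V(i, 0), V(i, 1), V(i, 2));
  // per-triangle centroid + bounding radius for pruning
  std::vector<V3> cen(nf);
  std::vector<double> rad(nf);
  for (int t = 0; t < nf; ++t) {
    V3 a = verts[F(t, 0)], b = verts[F(t, 1)], c = verts[F(t, 2)];
    V3 g = (1.0 / 3.0) * (a + b + c);
    cen[t] = g;
    rad[t] = std::sqrt(std::max({norm2(a - g), norm2(b - g), norm2(c - g)}));
  }
  NumericVector dist(np);
  NumericMatrix closest(np, 3);
  IntegerVector tri(np);
  for (int i = 0; i < np; ++i) {
    V3 p = v3(P(i, 0), P(i, 1), P(i, 2));
    double best = R_PosInf;
    V3 bq = v3(0, 0, 0);
    int bt = -1;
    for (int t = 0; t < nf; ++t) {
      double dc = std::sqrt(norm2(p - cen[t])) - rad[t];
      if (dc > 0.0 && dc * dc >= best) continue;
      V3 q = closest_on_triangle(p, verts[F(t, 0)], verts[F(t, 1)], verts[F(t, 2)]);
      double d2 = norm2(p - q);
      if (d2 < best) {
        best = d2;
        bq = q;
        bt = t;
      }
    }
    dist[i] = std::sqrt(best);
    closest(i, 0) = bq.x;
    closest(i, 1) = bq.y;
    closest(i, 2) = bq.z;
    tri[i] = bt;
  }
  return List::create(_["dist"] = dist, _["closest"] = closest, _["tri"] = tri);
}

// First positive-t ray/mesh intersection (Moller-Trumbore); t = -1 on miss.
// [[Rcpp::export]]
List cpp_ray_mesh(NumericMatrix O, NumericMatrix D, NumericMatrix V, IntegerMatrix F) {
  const int nr = O.nrow(), nf = F.nrow();
  std::vector<V3> verts(V.nrow());
  for (int i = 0; i < V.nrow(); ++i) verts[i] = v3(V(i, 0), V(i, 1), V(i, 2));
  NumericVector tout(nr);
  IntegerVector hit(nr);
  for (int i = 0; i < nr; ++i) {
    V3 o = v3(O(i, 0), O(i, 1), O(i, 2));
    V3 d = v3(D(i, 0), D(i, 1), D(i, 2));
    double best = R_PosInf;
    int bh = -1;
    for (int t = 0; t < nf; ++t) {
      V3 a = verts[F(t, 0)], e1 = verts[F(t, 1)] - a, e2 = verts[F(t, 2)] - a;
      V3 pv = cross(d, e2);
      double det = dot(e1, pv);
      if (std::fabs(det) < 1e-14) continue;
      double inv = 1.0 / det;
      V3 tv = o - a;
      double u = dot(tv, pv) * inv;
      if (u < -1e-10 || u > 1.0 + 1e-10) continue;
      V3 qv = cross(tv, e1);
      double v = dot(d, qv) * inv;
      if (v < -1e-10 || u + v > 1.0 + 1e-10) continue;
      double tt = dot(e2, qv) * inv;
      if (tt > 1e-10 && tt < best) {
        best = tt;
        bh = t;
      }
    }
    tout[i] = (bh >= 0) ? best : -1.0;
    hit[i] = bh;
  }
  return List::create(_["t"] = tout, _["tri"] = hit);
}

// ---------------------------------------------------------------------------
// Marching tetrahedra on a scalar grid.  Each cell is split into 5 tets with
// a parity flip between neighbouring cells so that shared-face diagonals
// coincide (crack-free).  Vertices are shared through a map keyed by the
// grid-point pair of the crossed edge, giving a watertight indexed mesh.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_marching_tets(NumericVector vals, IntegerVector dims, NumericVector spacing,
                       NumericVector origin, double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int64_t sx = 1, sy = nx, sz = (int64_t)nx * ny;
  std::vector<double> vx(nx), vy(ny), vz(nz);
  for (int i = 0; i < nx; ++i) vx[i] = origin[0] + i * spacing[0];
  for (int i = 0; i < ny; ++i) vy[i] = origin[1] + i * spacing[1];
  for (int i = 0; i < nz; ++i) vz[i] = origin[2] + i * spacing[2];

  std::unordered_map<uint64_t, int> edge_vert;
  std::vector<double> VX, VY, VZ;
  std::vector<int> FA, FB, FC;
  const double* f = vals.begin();

  auto gpos = [&](int64_t g) {
    int iz = (int)(g / sz);
    int64_t r = g - (int64_t)iz * sz;
    int iy = (int)(r / nx);
    int ix = (int)(r - (int64_t)iy * nx);
    return v3(vx[ix], vy[iy], vz[iz]);
  };
  auto edge_vertex = [&](int64_t ga, int64_t gb) {
    int64_t a = std::min(ga, gb), b = std::max(ga, gb);
    uint64_t key = (uint64_t)a * (uint64_t)((int64_t)nx * ny * nz) + (uint64_t)b;
    auto it = edge_vert.find(key);
    if (it != edge_vert.end()) return it->second;
    double va = f[a], vb = f[b];
    double t = (std::fabs(vb - va) < 1e-300) ? 0.5 : (iso - va) / (vb - va);
    t = std::min(1.0, std::max(0.0, t));
    V3 pa = gpos(a), pb = gpos(b);
    V3 p = pa + t * (pb - pa);
    int id = (int)VX.size();
    VX.push_back(p.x);
    VY.push_back(p.y);
    VZ.push_back(p.z);
    edge_vert[key] = id;
    return id;
  };
  auto emit = [&](int a, int b, int c) {
    FA.push_back(a);
    FB.push_back(b);
    FC.push_back(c);
  };
  auto vpos = [&](int id) { return v3(VX[id], VY[id], VZ[id]); };

  // tet decompositions: parity 0 central corners {0,3,5,6}; parity 1 {1,2,4,7}
  static const int tetsA[5][4] = {{0, 3, 5, 6}, {1, 0, 3, 5}, {2, 0, 3, 6}, {4, 0, 5, 6}, {7, 3, 5, 6}};
  static const int tetsB[5][4] = {{1, 2, 4, 7}, {0, 1, 2, 4}, {3, 1, 2, 7}, {5, 1, 4, 7}, {6, 2, 4, 7}};

  for (int iz = 0; iz + 1 < nz; ++iz)
    for (int iy = 0; iy + 1 < ny; ++iy)
      for (int ix = 0; ix + 1 < nx; ++ix) {
        int64_t g0 = ix * sx + (int64_t)iy * sy + (int64_t)iz * sz;
        int64_t corner[8];
        double cv[8];
        bool any_in = false, any_out = false;
        for (int k = 0; k < 8; ++k) {
          corner[k] = g0 + (k & 1) * sx + ((k >> 1) & 1) * sy + ((k >> 2) & 1) * sz;
          cv[k] = f[corner[k]];
          if (cv[k] > iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        const int(*tets)[4] = ((ix + iy + iz) & 1) ? tetsB : tetsA;
        for (int t = 0; t < 5; ++t) {
          int id[4] = {tets[t][0], tets[t][1], tets[t][2], tets[t][3]};
          bool in[4];
          int nin = 0;
          for (int k = 0; k < 4; ++k) {
            in[k] = cv[id[k]] > iso;
            nin += in[k];
          }
          if (nin == 0 || nin == 4) continue;
          int ins[4], outs[4], ni = 0, no = 0;
          for (int k = 0; k < 4; ++k) (in[k] ? ins[ni++] : outs[no++]) = id[k];
          if (nin == 1 || nin == 3) {
            int apex = (nin == 1) ? ins[0] : outs[0];
            int ring[3];
            int idx = 0;
            for (int k = 0; k < 4; ++k)
              if (id[k] != apex) ring[idx++] = id[k];
            int e0 = edge_vertex(corner[apex], corner[ring[0]]);
            int e1 = edge_vertex(corner[apex], corner[ring[1]]);
            int e2 = edge_vertex(corner[apex], corner[ring[2]]);
            V3 papex = gpos(corner[apex]);
            V3 g = (1.0 / 3.0) * (vpos(e0) + vpos(e1) + vpos(e2));
            V3 n = cross(vpos(e1) - vpos(e0), vpos(e2) - vpos(e0));
            // outward normal: from the inside region toward outside
            double s = dot(n, g - papex);
            bool flip = (nin == 1) ? (s < 0.0) : (s > 0.0);
            if (flip) emit(e0, e2, e1); else emit(e0, e1, e2);
          } else {  // 2 in, 2 out: quad loop e(a,c), e(a,d), e(b,d), e(b,c)
            int a = ins[0], b = ins[1], c = outs[0], d = outs[1];
            int q0 = edge_vertex(corner[a], corner[c]);
            int q1 = edge_vertex(corner[a], corner[d]);
            int q2 = edge_vertex(corner[b], corner[d]);
            int q3 = edge_vertex(corner[b], corner[c]);
            V3 ref = 0.5 * (gpos(corner[c]) + gpos(corner[d])) -
                     0.5 * (gpos(corner[a]) + gpos(corner[b]));
            V3 n = cross(vpos(q1) - vpos(q0), vpos(q2) - vpos(q0));
            if (dot(n, ref) < 0.0) {
              emit(q0, q2, q1);
              emit(q0, q3, q2);
            } else {
              emit(q0, q1, q2);
              emit(q0, q2, q3);
            }
          }
        }
      }

  int nv = (int)VX.size(), nt = (int)FA.size();
  NumericMatrix Vout(nv, 3);
  IntegerMatrix Fout(nt, 3);
  for (int i = 0; i < nv; ++i) {
    Vout(i, 0) = VX[i];
    Vout(i, 1) = VY[i];
    Vout(i, 2) = VZ[i];
  }
  for (int i = 0; i < nt; ++i) {
    Fout(i, 0) = FA[i];
    Fout(i, 1) = FB[i];
    Fout(i, 2) = FC[i];
  }
  return List::create(_["vertices"] = Vout, _["faces"] = Fout);
}

// ---------------------------------------------------------------------------
// Parity voxelization: one +x ray per (y,z) row of voxel centers; crossings
// with the closed surface toggle inside/outside.  Rows are nudged by a tiny
// irrational offset so that edge-grazing hits are measure-zero.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalVector cpp_voxelize(NumericMatrix V, IntegerMatrix F, IntegerVector dims,
                           NumericVector spacing, NumericVector origin) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], nf = F.nrow();
  LogicalVector out((int64_t)nx * ny * nz);
  std::fill(out.begin(), out.end(), FALSE);
  const double eps_y = 2.9289321881e-4 * spacing[1];
  const double eps_z = 4.1421356237e-4 * spacing[2];
  // triangle y/z bounds for pruning
  std::vector<double> ymin(nf), ymax(nf), zmin(nf), zmax(nf);
  for (int t = 0; t < nf; ++t) {
    double y0 = V(F(t, 0), 1), y1 = V(F(t, 1), 1), y2 = V(F(t, 2), 1);
    double z0 = V(F(t, 0), 2), z1 = V(F(t, 1), 2), z2 = V(F(t, 2), 2);
    ymin[t] = std::min({y0, y1, y2});
    ymax[t] = std::max({y0, y1, y2});
    zmin[t] = std::min({z0, z1, z2});
    zmax[t] = std::max({z0, z1, z2});
  }
  std::vector<double> xs;
  for (int iz = 0; iz < nz; ++iz) {
    double zc = origin[2] + iz * spacing[2] + eps_z;
    for (int iy = 0; iy < ny; ++iy) {
      double yc = origin[1] + iy * spacing[1] + eps_y;
      xs.clear();
      for (int t = 0; t < nf; ++t) {
        if (yc < ymin[t] || yc > ymax[t] || zc < zmin[t] || zc > zmax[t]) continue;
        // 2-D barycentric in (y,z)
        double ay = V(F(t, 0), 1), az = V(F(t, 0), 2);
        double by = V(F(t, 1), 1), bz = V(F(t, 1), 2);
        double cy = V(F(t, 2), 1), cz = V(F(t, 2), 2);
        double d = (by - ay) * (cz - az) - (cy - ay) * (bz - az);
        if (std::fabs(d) < 1e-300) continue;  // triangle parallel to ray
        double l1 = ((yc - ay) * (cz - az) - (cy - ay) * (zc - az)) / d;
        double l2 = ((by - ay) * (zc - az) - (yc - ay) * (bz - az)) / d;
        double l0 = 1.0 - l1 - l2;
        if (l0 < 0.0 || l1 < 0.0 || l2 < 0.0) continue;
        double x = l0 * V(F(t, 0), 0) + l1 * V(F(t, 1), 0) + l2 * V(F(t, 2), 0);
        xs.push_back(x);
      }
      if (xs.empty()) continue;
      std::sort(xs.begin(), xs.end());
      // parity fill: voxel center inside iff odd number of crossings below it
      int64_t base = (int64_t)iy * nx + (int64_t)iz * nx * ny;
      size_t k = 0;
      for (int ix = 0; ix < nx; ++ix) {
        double xc = origin[0] + ix * spacing[0];
        while (k < xs.size() && xs[k] < xc) ++k;
        if (k & 1) out[base + ix] = TRUE;
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Greedy Poisson-disk selection from a pre-shuffled candidate pool, with a
// geometrically shrinking radius until `n` points are accepted.
// Returns 0-based indices into the pool, or fewer than n if impossible.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_poisson_greedy(NumericMatrix P, int n, double r0, double rfloor,
                                 double shrink) {
  const int np = P.nrow();
  const double cell = std::max(rfloor / 1.7320508, 1e-9);
  auto key = [&](double x, double y, double z) {
    int64_t ix = (int64_t)std::floor(x / cell);
    int64_t iy = (int64_t)std::floor(y / cell);
    int64_t iz = (int64_t)std::floor(z / cell);
    return (uint64_t)(ix * 73856093LL) ^ (uint64_t)(iy * 19349663LL) ^
           (uint64_t)(iz * 83492791LL);
  };
  std::unordered_map<uint64_t, std::vector<int>> grid;
  std::vector<int> sel;
  std::vector<char> used(np, 0);
  sel.reserve(n);
  double r = r0;
  while ((int)sel.size() < n && r >= rfloor * 0.999) {
    double r2 = r * r;
    int reach = (int)std::ceil(r / cell);
    for (int i = 0; i < np && (int)sel.size() < n; ++i) {
      if (used[i]) continue;
      double x = P(i, 0), y = P(i, 1), z = P(i, 2);
      bool ok = true;
      int64_t cx = (int64_t)std::floor(x / cell), cy = (int64_t)std::floor(y / cell),
              cz = (int64_t)std::floor(z / cell);
      for (int dz = -reach; dz <= reach && ok; ++dz)
        for (int dy = -reach; dy <= reach && ok; ++dy)
          for (int dx = -reach; dx <= reach && ok; ++dx) {
            uint64_t k = (uint64_t)((cx + dx) * 73856093LL) ^
                         (uint64_t)((cy + dy) * 19349663LL) ^
                         (uint64_t)((cz + dz) * 83492791LL);
            auto it = grid.find(k);
            if (it == grid.end()) continue;
            for (int j : it->second) {
              double ddx = P(j, 0) - x, ddy = P(j, 1) - y, ddz = P(j, 2) - z;
              if (ddx * ddx + ddy * ddy + ddz * ddz < r2) {
                ok = false;
                break;
              }
            }
          }
      if (ok) {
        used[i] = 1;
        sel.push_back(i);
        grid[key(x, y, z)].push_back(i);
      }
    }
    r *= shrink;
  }
  return wrap(sel);
}

// All-points nearest neighbour (brute force).  Returns 0-based index of the
// nearest other point and its distance.
// [[Rcpp::export]]
List cpp_all_nn(NumericMatrix P) {
  const int n = P.nrow();
  IntegerVector idx(n);
  NumericVector dist(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int bj = -1;
    double x = P(i, 0), y = P(i, 1), z = P(i, 2);
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = P(j, 0) - x, dy = P(j, 1) - y, dz = P(j, 2) - z;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) {
        best = d2;
        bj = j;
      }
    }
    idx[i] = bj;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// Grid-accelerated closest-point-on-mesh for large meshes: triangles are
// binned by bounding box into a uniform grid; queries expand outward in
// Chebyshev rings until no closer cell can win.
// [[Rcpp::export]]
List cpp_closest_on_mesh_grid(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  const int np = P.nrow(), nf = F.nrow();
  if (nf == 0) stop("mesh has no faces");
  std::vector<V3> verts(V.nrow());
  for (int i = 0; i < V.nrow(); ++i) verts[i] = v3(V(i, 0), V(i, 1), V(i, 2));
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < V.nrow(); ++i) {
    lo[0] = std::min(lo[0], verts[i].x); hi[0] = std::max(hi[0], verts[i].x);
    lo[1] = std::min(lo[1], verts[i].y); hi[1] = std::max(hi[1], verts[i].y);
    lo[2] = std::min(lo[2], verts[i].z); hi[2] = std::max(hi[2], verts[i].z);
  }
  // cell size ~ mean triangle bounding-box diagonal, clamped to <=96 cells/axis
  double mean_diag = 0.0;
  for (int t = 0; t < nf; ++t) {
    V3 a = verts[F(t, 0)], b = verts[F(t, 1)], c = verts[F(t, 2)];
    double dx = std::max({a.x, b.x, c.x}) - std::min({a.x, b.x, c.x});
    double dy = std::max({a.y, b.y, c.y}) - std::min({a.y, b.y, c.y});
    double dz = std::max({a.z, b.z, c.z}) - std::min({a.z, b.z, c.z});
    mean_diag += std::sqrt(dx * dx + dy * dy + dz * dz);
  }
  mean_diag /= nf;
  double ext = std::max({hi[0] - lo[0], hi[1] - lo[1], hi[2] - lo[2], 1e-9});
  double cell = std::max(mean_diag, ext / 96.0);
  int ng[3];
  for (int d = 0; d < 3; ++d)
    ng[d] = std::max(1, (int)std::ceil((hi[d] - lo[d]) / cell) + 1);
  auto cidx = [&](int cx, int cy, int cz) {
    return (int64_t)cx + (int64_t)ng[0] * ((int64_t)cy + (int64_t)ng[1] * cz);
  };
  auto clampi = [](int v, int n) { return std::min(std::max(v, 0), n - 1); };
  std::vector<std::vector<int>> bins((int64_t)ng[0] * ng[1] * ng[2]);
  for (int t = 0; t < nf; ++t) {
    V3 a = verts[F(t, 0)], b = verts[F(t, 1)], c = verts[F(t, 2)];
    int x0 = clampi((int)((std::min({a.x, b.x, c.x}) - lo[0]) / cell), ng[0]);
    int x1 = clampi((int)((std::max({a.x, b.x, c.x}) - lo[0]) / cell), ng[0]);
    int y0 = clampi((int)((std::min({a.y, b.y, c.y}) - lo[1]) / cell), ng[1]);
    int y1 = clampi((int)((std::max({a.y, b.y, c.y}) - lo[1]) / cell), ng[1]);
    int z0 = clampi((int)((std::min({a.z, b.z, c.z}) - lo[2]) / cell), ng[2]);
    int z1 = clampi((int)((std::max({a.z, b.z, c.z}) - lo[2]) / cell), ng[2]);
    for (int cz = z0; cz <= z1; ++cz)
      for (int cy = y0; cy <= y1; ++cy)
        for (int cx = x0; cx <= x1; ++cx)
          bins[cidx(cx, cy, cz)].push_back(t);
  }
  NumericVector dist(np);
  NumericMatrix closest(np, 3);
  IntegerVector tri(np);
  int maxring = std::max({ng[0], ng[1], ng[2]});
  for (int i = 0; i < np; ++i) {
    V3 p = v3(P(i, 0), P(i, 1), P(i, 2));
    int px = clampi((int)((p.x - lo[0]) / cell), ng[0]);
    int py = clampi((int)((p.y - lo[1]) / cell), ng[1]);
    int pz = clampi((int)((p.z - lo[2]) / cell), ng[2]);
    double best = R_PosInf;
    V3 bq = v3(0, 0, 0);
    int bt = -1;
    for (int ring = 0; ring <= maxring; ++ring) {
      // all further rings are at least (ring-1)*cell away from p's cell
      if (bt >= 0 && (double)(ring - 1) * cell > std::sqrt(best)) break;
      int x0 = px - ring, x1 = px + ring;
      int y0 = py - ring, y1 = py + ring;
      int z0 = pz - ring, z1 = pz + ring;
      for (int cz = z0; cz <= z1; ++cz) {
        if (cz < 0 || cz >= ng[2]) continue;
        for (int cy = y0; cy <= y1; ++cy) {
          if (cy < 0 || cy >= ng[1]) continue;
          for (int cx = x0; cx <= x1; ++cx) {
            if (cx < 0 || cx >= ng[0]) continue;
            // shell only: skip interior cells already visited
            if (ring > 0 && cx != x0 && cx != x1 && cy != y0 && cy != y1 &&
                cz != z0 && cz != z1)
              continue;
            for (int t : bins[cidx(cx, cy, cz)]) {
              V3 q = closest_on_triangle(p, verts[F(t, 0)], verts[F(t, 1)],
                                         verts[F(t, 2)]);
              double d2 = norm2(p - q);
              if (d2 < best) {
                best = d2;
                bq = q;
                bt = t;
              }
            }
          }
        }
      }
    }
    dist[i] = std::sqrt(best);
    closest(i, 0) = bq.x;
    closest(i, 1) = bq.y;
    closest(i, 2) = bq.z;
    tri[i] = bt;
  }
  return List::create(_["dist"] = dist, _["closest"] = closest, _["tri"] = tri);
}

// Connected components of faces via shared edges (union-find).
// F is 0-based; returns a 0-based component id per face.
// [[Rcpp::export]]
IntegerVector cpp_face_components(IntegerMatrix F, int nverts) {
  const int nf = F.nrow();
  std::vector<int> parent(nf);
  for (int i = 0; i < nf; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int i) {
    while (parent[i] != i) {
      parent[i] = parent[parent[i]];
      i = parent[i];
    }
    return i;
  };
  std::unordered_map<uint64_t, int> first_face;
  first_face.reserve(3 * nf);
  for (int t = 0; t < nf; ++t) {
    for (int k = 0; k < 3; ++k) {
      int a = F(t, k), b = F(t, (k + 1) % 3);
      uint64_t key = (uint64_t)std::min(a, b) * (uint64_t)nverts +
                     (uint64_t)std::max(a, b);
      auto it = first_face.find(key);
      if (it == first_face.end()) {
        first_face[key] = t;
      } else {
        int ra = find(it->second), rb = find(t);
        if (ra != rb) parent[rb] = ra;
      }
    }
  }
  IntegerVector out(nf);
  for (int i = 0; i < nf; ++i) out[i] = find(i);
  return out;
}
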