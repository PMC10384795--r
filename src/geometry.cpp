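#include <Rcpp.h>
#include <vector>
#include <array>
#include <map>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Uniform-grid spatial index for k-NN and radius queries. Cells are hashed
// into buckets; queries visit only the cells overlapping the search ball.
// ---------------------------------------------------------------------------
namespace {

struct GridIndex {
  double h;                    // cell edge
  double lo[3];
  int dims[3];
  std::vector<std::vector<int> > cells;  // flattened (x + dims0*(y + dims1*z))
  const double *px, *py, *pz;
  int n;

  void build(const double *x, const double *y, const double *z, int n_,
             double cell) {
    px = x; py = y; pz = z; n = n_;
    h = cell;
    double hi[3];
    lo[0] = hi[0] = x[0]; lo[1] = hi[1] = y[0]; lo[2] = hi[2] = z[0];
    for (int i = 1; i < n; ++i) {
      lo[0] = std::min(lo[0], x[i]); hi[0] = std::max(hi[0], x[i]);
      lo[1] = std::min(lo[1], y[i]); hi[1] = std::max(hi[1], y[i]);
      lo[2] = std::min(lo[2], z[i]); hi[2] = std::max(hi[2], z[i]);
    }
    for (;;) {
      for (int d = 0; d < 3; ++d) {
        dims[d] = std::max(1, (int)((hi[d] - lo[d]) / h) + 1);
        dims[d] = std::min(dims[d], 1024);
      }
      if ((size_t)dims[0] * dims[1] * dims[2] <= 2000000u) break;
      h *= 2.0;  // keep the bucket array bounded
    }
    cells.assign((size_t)dims[0] * dims[1] * dims[2], std::vector<int>());
    for (int i = 0; i < n; ++i) cells[cell_of(x[i], y[i], z[i])].push_back(i);
  }

  inline int clampc(int v, int d) const {
    return v < 0 ? 0 : (v >= dims[d] ? dims[d] - 1 : v);
  }
  inline size_t cell_of(double x, double y, double z) const {
    const int cx = clampc((int)((x - lo[0]) / h), 0);
    const int cy = clampc((int)((y - lo[1]) / h), 1);
    const int cz = clampc((int)((z - lo[2]) / h), 2);
    return (size_t)cx + (size_t)dims[0] * ((size_t)cy + (size_t)dims[1] * cz);
  }

  // all points within radius r of (qx,qy,qz), appended to hits as (d2, idx)
  void query(double qx, double qy, double qz, double r,
             std::vector<std::pair<double,int> > &hits) const {
    const double r2 = r * r;
    const int x0 = clampc((int)((qx - r - lo[0]) / h), 0);
    const int x1 = clampc((int)((qx + r - lo[0]) / h), 0);
    const int y0 = clampc((int)((qy - r - lo[1]) / h), 1);
    const int y1 = clampc((int)((qy + r - lo[1]) / h), 1);
    const int z0 = clampc((int)((qz - r - lo[2]) / h), 2);
    const int z1 = clampc((int)((qz + r - lo[2]) / h), 2);
    for (int cz = z0; cz <= z1; ++cz)
      for (int cy = y0; cy <= y1; ++cy)
        for (int cx = x0; cx <= x1; ++cx) {
          const std::vector<int> &bucket =
            cells[(size_t)cx + (size_t)dims[0] * ((size_t)cy +
                  (size_t)dims[1] * cz)];
          for (size_t b = 0; b < bucket.size(); ++b) {
            const int j = bucket[b];
            const double dx = px[j]-qx, dy = py[j]-qy, dz = pz[j]-qz;
            const double dd = dx*dx + dy*dy + dz*dz;
            if (dd <= r2) hits.push_back(std::make_pair(dd, j));
          }
        }
  }
};

double heuristic_cell(const double *x, const double *y, const double *z,
                      int n, int per_cell) {
  double lo[3], hi[3];
  lo[0] = hi[0] = x[0]; lo[1] = hi[1] = y[0]; lo[2] = hi[2] = z[0];
  for (int i = 1; i < n; ++i) {
    lo[0] = std::min(lo[0], x[i]); hi[0] = std::max(hi[0], x[i]);
    lo[1] = std::min(lo[1], y[i]); hi[1] = std::max(hi[1], y[i]);
    lo[2] = std::min(lo[2], z[i]); hi[2] = std::max(hi[2], z[i]);
  }
  // geometric mean of the non-degenerate extents
  double prod = 1.0;
  int nd = 0;
  for (int d = 0; d < 3; ++d) {
    const double e = hi[d] - lo[d];
    if (e > 1e-12) { prod *= e; ++nd; }
  }
  if (nd == 0) return 1.0;
  const double vol = prod;
  double cell = std::pow(vol * per_cell / std::max(1, n), 1.0 / nd);
  return std::max(cell, 1e-9);
}

} // namespace

// k-nearest neighbours (self excluded), nearest first.
// [[Rcpp::export]]
IntegerMatrix cpp_knn(NumericMatrix X, int k) {
  const int n = X.nrow();
  if (k >= n) stop("k must be smaller than the number of points");
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) { x[i] = X(i,0); y[i] = X(i,1); z[i] = X(i,2); }
  GridIndex g;
  g.build(x.data(), y.data(), z.data(), n,
          heuristic_cell(x.data(), y.data(), z.data(), n, 2 * k));
  IntegerMatrix out(n, k);
  std::vector<std::pair<double,int> > hits;
  for (int i = 0; i < n; ++i) {
    double r = g.h;
    for (;;) {
      hits.clear();
      g.query(x[i], y[i], z[i], r, hits);
      if ((int)hits.size() >= k + 1) {
        std::partial_sort(hits.begin(), hits.begin() + k + 1, hits.end());
        // the k-th neighbour must lie inside the searched ball
        if (hits[k].first <= r * r) break;
      }
      r *= 2.0;
    }
    int written = 0;
    for (size_t j = 0; j < hits.size() && written < k; ++j) {
      if (hits[j].second == i) continue;  // self
      out(i, written++) = hits[j].second + 1;
    }
  }
  return out;
}

// Radius search: 1-based indices of X within `radius` of each query row,
// ordered by increasing distance.
// [[Rcpp::export]]
List cpp_radius_neighbors(NumericMatrix X, NumericMatrix Q, double radius) {
  const int n = X.nrow(), m = Q.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) { x[i] = X(i,0); y[i] = X(i,1); z[i] = X(i,2); }
  GridIndex g;
  g.build(x.data(), y.data(), z.data(), n, std::max(radius, 1e-9));
  List out(m);
  std::vector<std::pair<double,int> > hits;
  for (int i = 0; i < m; ++i) {
    hits.clear();
    g.query(Q(i,0), Q(i,1), Q(i,2), radius, hits);
    std::sort(hits.begin(), hits.end());
    IntegerVector idx(hits.size());
    for (size_t j = 0; j < hits.size(); ++j) idx[j] = hits[j].second + 1;
    out[i] = idx;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Incremental 3D convex hull. Returns an m x 3 matrix of 1-based vertex
// indices; triangles are oriented with outward normals. Points interior to
// the hull simply do not appear among the triangle vertices.
// ---------------------------------------------------------------------------
namespace {

struct Face {
  int a, b, c;
  double nx, ny, nz, off;  // plane: n . p = off
  bool alive;
};

inline void face_plane(Face &f, const std::vector<double> &px,
                       const std::vector<double> &py,
                       const std::vector<double> &pz,
                       double ix, double iy, double iz) {
  const double ux = px[f.b]-px[f.a], uy = py[f.b]-py[f.a], uz = pz[f.b]-pz[f.a];
  const double vx = px[f.c]-px[f.a], vy = py[f.c]-py[f.a], vz = pz[f.c]-pz[f.a];
  f.nx = uy*vz - uz*vy;
  f.ny = uz*vx - ux*vz;
  f.nz = ux*vy - uy*vx;
  f.off = f.nx*px[f.a] + f.ny*py[f.a] + f.nz*pz[f.a];
  // orient away from a fixed interior point
  if (f.nx*ix + f.ny*iy + f.nz*iz > f.off) {
    std::swap(f.b, f.c);
    f.nx = -f.nx; f.ny = -f.ny; f.nz = -f.nz; f.off = -f.off;
  }
}

} // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_convhull3(NumericMatrix P) {
  const int n = P.nrow();
  if (n < 4) stop("convex hull needs at least 4 points");
  std::vector<double> px(n), py(n), pz(n);
  double scale = 0.0;
  for (int i = 0; i < n; ++i) {
    px[i] = P(i,0); py[i] = P(i,1); pz[i] = P(i,2);
    scale = std::max(scale, std::fabs(px[i]));
    scale = std::max(scale, std::fabs(py[i]));
    scale = std::max(scale, std::fabs(pz[i]));
  }
  const double eps = 1e-10 * std::max(scale, 1e-12);

  // initial tetrahedron: extreme point pair, then farthest from line, plane
  int i0 = 0, i1 = -1, i2 = -1, i3 = -1;
  for (int i = 1; i < n; ++i) if (px[i] < px[i0]) i0 = i;
  double best = -1.0;
  for (int i = 0; i < n; ++i) {
    const double dx = px[i]-px[i0], dy = py[i]-py[i0], dz = pz[i]-pz[i0];
    const double dd = dx*dx+dy*dy+dz*dz;
    if (dd > best) { best = dd; i1 = i; }
  }
  if (best <= eps*eps) stop("degenerate point set: all points coincident");
  const double lx = px[i1]-px[i0], ly = py[i1]-py[i0], lz = pz[i1]-pz[i0];
  best = -1.0;
  for (int i = 0; i < n; ++i) {
    const double dx = px[i]-px[i0], dy = py[i]-py[i0], dz = pz[i]-pz[i0];
    const double cx = ly*dz-lz*dy, cy = lz*dx-lx*dz, cz = lx*dy-ly*dx;
    const double dd = cx*cx+cy*cy+cz*cz;
    if (dd > best) { best = dd; i2 = i; }
  }
  if (best <= eps*eps) stop("degenerate point set: all points collinear");
  {
    const double ux = px[i1]-px[i0], uy = py[i1]-py[i0], uz = pz[i1]-pz[i0];
    const double vx = px[i2]-px[i0], vy = py[i2]-py[i0], vz = pz[i2]-pz[i0];
    const double nx = uy*vz-uz*vy, ny = uz*vx-ux*vz, nz = ux*vy-uy*vx;
    const double nn = std::sqrt(nx*nx+ny*ny+nz*nz);
    best = -1.0;
    for (int i = 0; i < n; ++i) {
      const double d = std::fabs(nx*(px[i]-px[i0]) + ny*(py[i]-py[i0]) +
                                 nz*(pz[i]-pz[i0])) / nn;
      if (d > best) { best = d; i3 = i; }
    }
    if (best <= eps) stop("degenerate point set: all points coplanar");
  }

  const double ix = (px[i0]+px[i1]+px[i2]+px[i3])/4.0;
  const double iy = (py[i0]+py[i1]+py[i2]+py[i3])/4.0;
  const double iz = (pz[i0]+pz[i1]+pz[i2]+pz[i3])/4.0;

  std::vector<Face> faces;
  faces.reserve(4 * (size_t)n);
  int init[4][3] = {{i0,i1,i2},{i0,i1,i3},{i0,i2,i3},{i1,i2,i3}};
  for (int f = 0; f < 4; ++f) {
    Face fc; fc.a = init[f][0]; fc.b = init[f][1]; fc.c = init[f][2]; fc.alive = true;
    face_plane(fc, px, py, pz, ix, iy, iz);
    faces.push_back(fc);
  }

  std::vector<int> visible;
  std::map<std::pair<int,int>, int> edge_count;
  for (int p = 0; p < n; ++p) {
    if (p == i0 || p == i1 || p == i2 || p == i3) continue;
    visible.clear();
    for (size_t f = 0; f < faces.size(); ++f) {
      if (!faces[f].alive) continue;
      const double nn = std::sqrt(faces[f].nx*faces[f].nx +
                                  faces[f].ny*faces[f].ny +
                                  faces[f].nz*faces[f].nz);
      const double d = (faces[f].nx*px[p] + faces[f].ny*py[p] +
                        faces[f].nz*pz[p] - faces[f].off) / nn;
      if (d > eps) visible.push_back((int)f);
    }
    if (visible.empty()) continue;  // interior point
    edge_count.clear();
    for (size_t v = 0; v < visible.size(); ++v) {
      const Face &f = faces[visible[v]];
      int e[3][2] = {{f.a,f.b},{f.b,f.c},{f.c,f.a}};
      for (int j = 0; j < 3; ++j) {
        std::pair<int,int> key(std::min(e[j][0], e[j][1]),
                               std::max(e[j][0], e[j][1]));
        edge_count[key] += 1;
      }
      faces[visible[v]].alive = false;
    }
    for (std::map<std::pair<int,int>, int>::iterator it = edge_count.begin();
         it != edge_count.end(); ++it) {
      if (it->second != 1) continue;  // internal edge of the visible patch
      Face fc; fc.a = it->first.first; fc.b = it->first.second; fc.c = p;
      fc.alive = true;
      face_plane(fc, px, py, pz, ix, iy, iz);
      faces.push_back(fc);
    }
  }

  int m = 0;
  for (size_t f = 0; f < faces.size(); ++f) if (faces[f].alive) ++m;
  IntegerMatrix out(m, 3);
  int r = 0;
  for (size_t f = 0; f < faces.size(); ++f) {
    if (!faces[f].alive) continue;
    out(r,0) = faces[f].a + 1; out(r,1) = faces[f].b + 1; out(r,2) = faces[f].c + 1;
    ++r;
  }
  return out;
}

// ---------------------------------------------------------------------------
// 2D Delaunay triangulation (Bowyer-Watson). Input must be free of duplicate
// points. Returns m x 3 matrix of 1-based indices, CCW oriented.
// Cocircular degeneracies (regular grids) are handled by counting on-circle
// points as in-circle, which keeps the cavity star-shaped.
// ---------------------------------------------------------------------------
namespace {

struct Tri {
  int a, b, c;
  double cx, cy, r2;
  bool alive;
};

inline bool circumcircle(int ia, int ib, int ic,
                         const std::vector<double> &x,
                         const std::vector<double> &y, Tri &t) {
  const double ax = x[ia], ay = y[ia], bx = x[ib], by = y[ib],
               ccx = x[ic], ccy = y[ic];
  const double d = 2.0 * (ax*(by-ccy) + bx*(ccy-ay) + ccx*(ay-by));
  if (d == 0.0) return false;
  const double a2 = ax*ax+ay*ay, b2 = bx*bx+by*by, c2 = ccx*ccx+ccy*ccy;
  t.cx = (a2*(by-ccy) + b2*(ccy-ay) + c2*(ay-by)) / d;
  t.cy = (a2*(ccx-bx) + b2*(ax-ccx) + c2*(bx-ax)) / d;
  const double dx = ax - t.cx, dy = ay - t.cy;
  t.r2 = dx*dx + dy*dy;
  return true;
}

} // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_delaunay2(NumericMatrix P) {
  const int n = P.nrow();
  if (n < 3) stop("triangulation needs at least 3 points");
  // normalize into [0,1] for numeric conditioning
  double minx = P(0,0), maxx = P(0,0), miny = P(0,1), maxy = P(0,1);
  for (int i = 1; i < n; ++i) {
    minx = std::min(minx, P(i,0)); maxx = std::max(maxx, P(i,0));
    miny = std::min(miny, P(i,1)); maxy = std::max(maxy, P(i,1));
  }
  const double span = std::max(std::max(maxx-minx, maxy-miny), 1e-300);
  std::vector<double> x(n+3), y(n+3);
  for (int i = 0; i < n; ++i) {
    x[i] = (P(i,0)-minx)/span;
    y[i] = (P(i,1)-miny)/span;
  }
  // super triangle comfortably enclosing the unit square
  x[n]   = -10.0; y[n]   = -10.0;
  x[n+1] =  21.0; y[n+1] = -10.0;
  x[n+2] =  0.5;  y[n+2] =  21.0;

  std::vector<Tri> tris;
  tris.reserve(4 * (size_t)n);
  Tri t0; t0.a = n; t0.b = n+1; t0.c = n+2; t0.alive = true;
  circumcircle(t0.a, t0.b, t0.c, x, y, t0);
  tris.push_back(t0);

  const double eps = 1e-12;
  std::vector<int> bad;
  std::map<std::pair<int,int>, int> edge_count;
  for (int p = 0; p < n; ++p) {
    bad.clear();
    for (size_t t = 0; t < tris.size(); ++t) {
      if (!tris[t].alive) continue;
      const double dx = x[p]-tris[t].cx, dy = y[p]-tris[t].cy;
      if (dx*dx + dy*dy <= tris[t].r2 + eps) bad.push_back((int)t);
    }
    if (bad.empty()) stop("Delaunay insertion failed (duplicate point?)");
    edge_count.clear();
    for (size_t b = 0; b < bad.size(); ++b) {
      const Tri &t = tris[bad[b]];
      int e[3][2] = {{t.a,t.b},{t.b,t.c},{t.c,t.a}};
      for (int j = 0; j < 3; ++j) {
        std::pair<int,int> key(std::min(e[j][0], e[j][1]),
                               std::max(e[j][0], e[j][1]));
        edge_count[key] += 1;
      }
      tris[bad[b]].alive = false;
    }
    for (std::map<std::pair<int,int>, int>::iterator it = edge_count.begin();
         it != edge_count.end(); ++it) {
      if (it->second != 1) continue;
      Tri nt; nt.a = it->first.first; nt.b = it->first.second; nt.c = p;
      nt.alive = true;
      // enforce CCW
      const double cr = (x[nt.b]-x[nt.a])*(y[nt.c]-y[nt.a]) -
                        (x[nt.c]-x[nt.a])*(y[nt.b]-y[nt.a]);
      if (cr < 0) std::swap(nt.b, nt.c);
      if (!circumcircle(nt.a, nt.b, nt.c, x, y, nt)) continue;  // degenerate sliver
      tris.push_back(nt);
    }
  }

  int m = 0;
  for (size_t t = 0; t < tris.size(); ++t)
    if (tris[t].alive && tris[t].a < n && tris[t].b < n && tris[t].c < n) ++m;
  IntegerMatrix out(m, 3);
  int r = 0;
  for (size_t t = 0; t < tris.size(); ++t) {
    if (!(tris[t].alive && tris[t].a < n && tris[t].b < n && tris[t].c < n))
      continue;
    out(r,0) = tris[t].a + 1; out(r,1) = tris[t].b + 1; out(r,2) = tris[t].c + 1;
    ++r;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Progressive Poisson-disk thinning for surface up-sampling: accept
// candidates whose distance to every existing/accepted point exceeds the
// current radius, relaxing the radius geometrically until `n_target`
// candidates are accepted. Returns 1-based candidate indices in acceptance
// order. Early rounds give blue-noise spacing; later rounds fill in.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerVector cpp_poisson_thin(NumericMatrix X, NumericMatrix cand,
                               double r0, int n_target) {
  const int n = X.nrow(), m = cand.nrow();
  if (n_target > m) stop("fewer candidates than requested points");
  std::vector<double> x, y, z;
  x.reserve(n + n_target); y.reserve(n + n_target); z.reserve(n + n_target);
  for (int i = 0; i < n; ++i) {
    x.push_back(X(i,0)); y.push_back(X(i,1)); z.push_back(X(i,2));
  }
  std::vector<int> accepted;
  accepted.reserve(n_target);
  std::vector<char> used(m, 0);
  double rt = r0;
  while ((int)accepted.size() < n_target && rt > 1e-9 * (r0 + 1e-300)) {
    // rebuild the grid at the current radius over existing + accepted
    GridIndex g;
    g.build(x.data(), y.data(), z.data(), (int)x.size(),
            std::max(rt, 1e-9));
    std::vector<std::pair<double,int> > hits;
    const double rt2 = rt * rt;
    for (int i = 0; i < m && (int)accepted.size() < n_target; ++i) {
      if (used[i]) continue;
      const double cx = cand(i,0), cy = cand(i,1), cz = cand(i,2);
      hits.clear();
      // grid built once per round: also check points accepted this round
      g.query(cx, cy, cz, rt, hits);
      bool ok = hits.empty();
      if (ok) {
        // linear check against this round's additions (not in the grid)
        for (size_t a = g.n; a < x.size(); ++a) {
          const double dx = x[a]-cx, dy = y[a]-cy, dz = z[a]-cz;
          if (dx*dx + dy*dy + dz*dz <= rt2) { ok = false; break; }
        }
      }
      if (ok) {
        used[i] = 1;
        accepted.push_back(i + 1);
        x.push_back(cx); y.push_back(cy); z.push_back(cz);
      }
    }
    rt *= 0.8;
  }
  // radius exhausted: fill with arbitrary unused candidates
  for (int i = 0; i < m && (int)accepted.size() < n_target; ++i)
    if (!used[i]) { used[i] = 1; accepted.push_back(i + 1); }
  return IntegerVector(accepted.begin(), accepted.end());
}
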