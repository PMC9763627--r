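// Core numerical kernels for the cross-bridge migration model (CBMM):
// mesh geometry, point-triangle contact queries, coarse-grained membrane
// forces, Morse-type adhesion, intercellular Couette friction, finite-volume
// surface transport of mobile cross-bridge density, and the explicit
// time-stepping loop used by the doublet protocols.
//
// All quantities are SI internally. Vertex/triangle indices arriving from R
// are 1-based and converted on entry; indices returned to R are 1-based.

#include <Rcpp.h>
#include <array>
#include <cmath>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <unordered_map>
#include <limits>

using namespace Rcpp;

// ---------------------------------------------------------------- vec3 utils

static inline void vset(double* a, double x, double y, double z) {
  a[0] = x; a[1] = y; a[2] = z;
}
static inline void vcopy(double* a, const double* b) {
  a[0] = b[0]; a[1] = b[1]; a[2] = b[2];
}
static inline void vsub(double* r, const double* a, const double* b) {
  r[0] = a[0] - b[0]; r[1] = a[1] - b[1]; r[2] = a[2] - b[2];
}
static inline void vadds(double* r, const double* a, double s) {
  r[0] += a[0] * s; r[1] += a[1] * s; r[2] += a[2] * s;
}
static inline double vdot(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void vcross(double* r, const double* a, const double* b) {
  r[0] = a[1] * b[2] - a[2] * b[1];
  r[1] = a[2] * b[0] - a[0] * b[2];
  r[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double vnorm(const double* a) { return std::sqrt(vdot(a, a)); }

// ------------------------------------------------------------- mesh topology

struct Topo {
  int nv = 0, nt = 0, ne = 0, nq = 0;
  std::vector<int> T;   // 3*nt, 0-based
  std::vector<int> E;   // 2*ne
  std::vector<int> Q;   // 4*nq dihedral quads (i, j, k, l)
  std::vector<double> rest_len;       // ne
  std::vector<double> rest_theta;     // nq
  std::vector<double> rest_ct, rest_st;  // cos/sin of rest dihedrals
  std::vector<double> rest_tri_area;  // nt
  std::vector<int> tri_edge;          // 3*nt: edge index of each tri side
  double rest_area = 0.0, rest_vol = 0.0;
};

// map each triangle side to its undirected edge index (for the transport
// finite-volume assembly); built once per topology
static void buildTriEdge(Topo& tp) {
  std::unordered_map<int64_t, int> eidx;
  eidx.reserve(2 * tp.ne);
  for (int e = 0; e < tp.ne; ++e) {
    const int i = tp.E[2 * e], j = tp.E[2 * e + 1];
    eidx[(static_cast<int64_t>(std::min(i, j)) << 32) |
         static_cast<int64_t>(std::max(i, j))] = e;
  }
  tp.tri_edge.assign(3 * tp.nt, -1);
  for (int t = 0; t < tp.nt; ++t)
    for (int c = 0; c < 3; ++c) {
      const int a = tp.T[3 * t + c], b = tp.T[3 * t + (c + 1) % 3];
      auto it = eidx.find((static_cast<int64_t>(std::min(a, b)) << 32) |
                          static_cast<int64_t>(std::max(a, b)));
      if (it != eidx.end()) tp.tri_edge[3 * t + c] = it->second;
    }
}

static Topo topoFromList(const List& mesh) {
  Topo tp;
  IntegerMatrix T = mesh["triangles"];
  IntegerMatrix E = mesh["edges"];
  IntegerMatrix Q = mesh["dihedral_quads"];
  tp.nt = T.nrow(); tp.ne = E.nrow(); tp.nq = Q.nrow();
  tp.nv = as<int>(mesh["n_vertices"]);
  tp.T.resize(3 * tp.nt); tp.E.resize(2 * tp.ne); tp.Q.resize(4 * tp.nq);
  for (int t = 0; t < tp.nt; ++t)
    for (int k = 0; k < 3; ++k) tp.T[3 * t + k] = T(t, k) - 1;
  for (int e = 0; e < tp.ne; ++e)
    for (int k = 0; k < 2; ++k) tp.E[2 * e + k] = E(e, k) - 1;
  for (int q = 0; q < tp.nq; ++q)
    for (int k = 0; k < 4; ++k) tp.Q[4 * q + k] = Q(q, k) - 1;
  NumericVector rl = mesh["rest_edge_lengths"];
  NumericVector rt = mesh["rest_dihedral_angles"];
  NumericVector ra = mesh["rest_tri_areas"];
  tp.rest_len.assign(rl.begin(), rl.end());
  tp.rest_theta.assign(rt.begin(), rt.end());
  tp.rest_tri_area.assign(ra.begin(), ra.end());
  tp.rest_area = as<double>(mesh["rest_total_area"]);
  tp.rest_vol = as<double>(mesh["rest_total_volume"]);
  tp.rest_ct.resize(tp.nq);
  tp.rest_st.resize(tp.nq);
  for (int q = 0; q < tp.nq; ++q) {
    tp.rest_ct[q] = std::cos(tp.rest_theta[q]);
    tp.rest_st[q] = std::sin(tp.rest_theta[q]);
  }
  buildTriEdge(tp);
  return tp;
}

// ------------------------------------------------------------ mesh geometry

struct Geom {
  std::vector<double> tri_area;  // nt
  std::vector<double> Ai;        // nv, median-dual areas
  std::vector<double> nrm;       // 3*nv, unit outward vertex normals
  double area = 0.0, vol = 0.0;
};

static void computeGeom(const double* X, const Topo& tp, Geom& g) {
  g.tri_area.assign(tp.nt, 0.0);
  g.Ai.assign(tp.nv, 0.0);
  g.nrm.assign(3 * tp.nv, 0.0);
  g.area = 0.0; g.vol = 0.0;
  double ab[3], ac[3], n[3];
  for (int t = 0; t < tp.nt; ++t) {
    const int ia = tp.T[3 * t], ib = tp.T[3 * t + 1], ic = tp.T[3 * t + 2];
    const double *a = X + 3 * ia, *b = X + 3 * ib, *c = X + 3 * ic;
    vsub(ab, b, a); vsub(ac, c, a); vcross(n, ab, ac);
    const double At = 0.5 * vnorm(n);
    g.tri_area[t] = At;
    g.area += At;
    // signed volume of tetrahedron (origin, a, b, c); outward orientation
    double bc[3]; vcross(bc, b, c);
    g.vol += vdot(a, bc) / 6.0;
    const double third = At / 3.0;
    g.Ai[ia] += third; g.Ai[ib] += third; g.Ai[ic] += third;
    for (int k = 0; k < 3; ++k) {
      g.nrm[3 * ia + k] += n[k];
      g.nrm[3 * ib + k] += n[k];
      g.nrm[3 * ic + k] += n[k];
    }
  }
  for (int i = 0; i < tp.nv; ++i) {
    double* ni = g.nrm.data() + 3 * i;
    const double len = vnorm(ni);
    if (len > 0) { ni[0] /= len; ni[1] /= len; ni[2] /= len; }
  }
}

// [[Rcpp::export]]
List cpp_vertex_geometry(NumericMatrix V, IntegerMatrix T) {
  const int nv = V.nrow(), nt = T.nrow();
  Topo tp; tp.nv = nv; tp.nt = nt; tp.T.resize(3 * nt);
  for (int t = 0; t < nt; ++t)
    for (int k = 0; k < 3; ++k) tp.T[3 * t + k] = T(t, k) - 1;
  std::vector<double> X(3 * nv);
  for (int i = 0; i < nv; ++i)
    for (int k = 0; k < 3; ++k) X[3 * i + k] = V(i, k);
  Geom g; computeGeom(X.data(), tp, g);
  NumericMatrix nrm(nv, 3);
  for (int i = 0; i < nv; ++i)
    for (int k = 0; k < 3; ++k) nrm(i, k) = g.nrm[3 * i + k];
  return List::create(
    _["tri_areas"] = NumericVector(g.tri_area.begin(), g.tri_area.end()),
    _["dual_areas"] = NumericVector(g.Ai.begin(), g.Ai.end()),
    _["normals"] = nrm,
    _["total_area"] = g.area,
    _["total_volume"] = g.vol);
}

// ------------------------------------------------- point-triangle distance

// Closest point on triangle (a,b,c) to p (Ericson, Real-Time Collision
// Detection). Writes closest point into q and barycentric coords into bc.
static void closestPtTri(const double* p, const double* a, const double* b,
                         const double* c, double* q, double* bc) {
  double ab[3], ac[3], ap[3];
  vsub(ab, b, a); vsub(ac, c, a); vsub(ap, p, a);
  const double d1 = vdot(ab, ap), d2 = vdot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) { vcopy(q, a); vset(bc, 1, 0, 0); return; }
  double bp[3]; vsub(bp, p, b);
  const double d3 = vdot(ab, bp), d4 = vdot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) { vcopy(q, b); vset(bc, 0, 1, 0); return; }
  const double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    const double v = d1 / (d1 - d3);
    vset(q, a[0] + v * ab[0], a[1] + v * ab[1], a[2] + v * ab[2]);
    vset(bc, 1 - v, v, 0); return;
  }
  double cp[3]; vsub(cp, p, c);
  const double d5 = vdot(ab, cp), d6 = vdot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) { vcopy(q, c); vset(bc, 0, 0, 1); return; }
  const double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    const double w = d2 / (d2 - d6);
    vset(q, a[0] + w * ac[0], a[1] + w * ac[1], a[2] + w * ac[2]);
    vset(bc, 1 - w, 0, w); return;
  }
  const double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    const double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    vset(q, b[0] + w * (c[0] - b[0]), b[1] + w * (c[1] - b[1]),
         b[2] + w * (c[2] - b[2]));
    vset(bc, 0, 1 - w, w); return;
  }
  const double denom = 1.0 / (va + vb + vc);
  const double v = vb * denom, w = vc * denom;
  vset(q, a[0] + ab[0] * v + ac[0] * w, a[1] + ab[1] * v + ac[1] * w,
       a[2] + ab[2] * v + ac[2] * w);
  vset(bc, 1 - v - w, v, w);
}

// ------------------------------------------------------------- spatial grid

// Dense uniform grid over the target body's bounding box, rebuilt by
// counting sort with reusable buffers (no per-step allocation churn after
// the first build). Cell size >= query cutoff, so a query point only needs
// its 27-cell neighbourhood.
struct DenseGrid {
  double h = 1.0, org[3] = {0, 0, 0};
  int nx = 1, ny = 1, nz = 1;
  std::vector<int> start;   // ncells + 1
  std::vector<int> items;   // item indices, cell-sorted
  std::vector<int> scratch; // per-item cell ids (points) / counts
  inline int clampi(int v, int hi) const {
    return v < 0 ? 0 : (v >= hi ? hi - 1 : v);
  }
  inline bool cellOf(const double* p, int& ix, int& iy, int& iz) const {
    ix = static_cast<int>(std::floor((p[0] - org[0]) / h));
    iy = static_cast<int>(std::floor((p[1] - org[1]) / h));
    iz = static_cast<int>(std::floor((p[2] - org[2]) / h));
    return ix >= -1 && ix <= nx && iy >= -1 && iy <= ny && iz >= -1 &&
           iz <= nz;
  }
  inline int cid(int ix, int iy, int iz) const {
    return (iz * ny + iy) * nx + ix;
  }
};

static void gridFrame(DenseGrid& gr, const double* X, int n, double h) {
  double lo[3] = {X[0], X[1], X[2]}, hi[3] = {X[0], X[1], X[2]};
  for (int i = 1; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      lo[k] = std::min(lo[k], X[3 * i + k]);
      hi[k] = std::max(hi[k], X[3 * i + k]);
    }
  gr.h = h;
  for (int k = 0; k < 3; ++k) gr.org[k] = lo[k] - h;
  gr.nx = static_cast<int>((hi[0] - gr.org[0]) / h) + 2;
  gr.ny = static_cast<int>((hi[1] - gr.org[1]) / h) + 2;
  gr.nz = static_cast<int>((hi[2] - gr.org[2]) / h) + 2;
}

// triangles are inserted into every cell their AABB covers
static void buildTriGrid(const double* Xt, const Topo& tp, double h,
                         DenseGrid& gr) {
  // cell size must also cover a whole triangle AABB span so insertion
  // stays cheap; enlarge h to the largest triangle extent
  double maxext = h;
  for (int t = 0; t < tp.nt; ++t) {
    const double* v0 = Xt + 3 * tp.T[3 * t];
    const double* v1 = Xt + 3 * tp.T[3 * t + 1];
    const double* v2 = Xt + 3 * tp.T[3 * t + 2];
    for (int k = 0; k < 3; ++k) {
      const double lo = std::min(v0[k], std::min(v1[k], v2[k]));
      const double hi = std::max(v0[k], std::max(v1[k], v2[k]));
      maxext = std::max(maxext, hi - lo);
    }
  }
  gridFrame(gr, Xt, tp.nv, maxext);
  const int ncell = gr.nx * gr.ny * gr.nz;
  gr.start.assign(ncell + 1, 0);
  // count pass then fill pass over (triangle, covered cell) incidences
  auto cellsOfTri = [&](int t, int& x0, int& x1, int& y0, int& y1, int& z0,
                        int& z1) {
    const double* v0 = Xt + 3 * tp.T[3 * t];
    const double* v1 = Xt + 3 * tp.T[3 * t + 1];
    const double* v2 = Xt + 3 * tp.T[3 * t + 2];
    double lo[3], hi[3];
    for (int k = 0; k < 3; ++k) {
      lo[k] = std::min(v0[k], std::min(v1[k], v2[k]));
      hi[k] = std::max(v0[k], std::max(v1[k], v2[k]));
    }
    x0 = gr.clampi(static_cast<int>((lo[0] - gr.org[0]) / gr.h), gr.nx);
    y0 = gr.clampi(static_cast<int>((lo[1] - gr.org[1]) / gr.h), gr.ny);
    z0 = gr.clampi(static_cast<int>((lo[2] - gr.org[2]) / gr.h), gr.nz);
    x1 = gr.clampi(static_cast<int>((hi[0] - gr.org[0]) / gr.h), gr.nx);
    y1 = gr.clampi(static_cast<int>((hi[1] - gr.org[1]) / gr.h), gr.ny);
    z1 = gr.clampi(static_cast<int>((hi[2] - gr.org[2]) / gr.h), gr.nz);
  };
  for (int t = 0; t < tp.nt; ++t) {
    int x0, x1, y0, y1, z0, z1;
    cellsOfTri(t, x0, x1, y0, y1, z0, z1);
    for (int iz = z0; iz <= z1; ++iz)
      for (int iy = y0; iy <= y1; ++iy)
        for (int ix = x0; ix <= x1; ++ix) ++gr.start[gr.cid(ix, iy, iz) + 1];
  }
  for (int c = 0; c < ncell; ++c) gr.start[c + 1] += gr.start[c];
  gr.items.resize(gr.start[ncell]);
  gr.scratch.assign(ncell, 0);
  for (int t = 0; t < tp.nt; ++t) {
    int x0, x1, y0, y1, z0, z1;
    cellsOfTri(t, x0, x1, y0, y1, z0, z1);
    for (int iz = z0; iz <= z1; ++iz)
      for (int iy = y0; iy <= y1; ++iy)
        for (int ix = x0; ix <= x1; ++ix) {
          const int c = gr.cid(ix, iy, iz);
          gr.items[gr.start[c] + gr.scratch[c]++] = t;
        }
  }
}

static void buildPointGrid(const double* Xt, int nv, double h,
                           DenseGrid& gr) {
  gridFrame(gr, Xt, nv, h);
  const int ncell = gr.nx * gr.ny * gr.nz;
  gr.start.assign(ncell + 1, 0);
  gr.scratch.resize(nv);
  for (int i = 0; i < nv; ++i) {
    int ix, iy, iz;
    gr.cellOf(Xt + 3 * i, ix, iy, iz);
    const int c = gr.cid(gr.clampi(ix, gr.nx), gr.clampi(iy, gr.ny),
                         gr.clampi(iz, gr.nz));
    gr.scratch[i] = c;
    ++gr.start[c + 1];
  }
  for (int c = 0; c < ncell; ++c) gr.start[c + 1] += gr.start[c];
  gr.items.resize(nv);
  std::vector<int> fill(ncell, 0);
  for (int i = 0; i < nv; ++i) {
    const int c = gr.scratch[i];
    gr.items[gr.start[c] + fill[c]++] = i;
  }
}

// ------------------------------------------------------------ contact query

struct ContactVTS {
  std::vector<int> tri;      // nearest triangle, -1 when none within cutoff
  std::vector<double> dist;  // rVTS
  std::vector<double> dir;   // 3*nv, unit vector vertex -> closest point
  std::vector<double> bary;  // 3*nv
};

// full query against the target triangulation within rcutoff
static void contactQueryVTS(const double* Xs, int ns, const double* Xt,
                            const Topo& tpt, double rcutoff, ContactVTS& cm,
                            DenseGrid& gr) {
  cm.tri.assign(ns, -1);
  cm.dist.assign(ns, std::numeric_limits<double>::infinity());
  cm.dir.assign(3 * ns, 0.0);
  cm.bary.assign(3 * ns, 0.0);
  buildTriGrid(Xt, tpt, rcutoff, gr);
  double q[3], bc[3], d[3];
  for (int i = 0; i < ns; ++i) {
    const double* p = Xs + 3 * i;
    int ix, iy, iz;
    if (!gr.cellOf(p, ix, iy, iz)) continue;
    double best = rcutoff;
    int bestTri = -1;
    double bestDir[3] = {0, 0, 0}, bestBc[3] = {0, 0, 0};
    for (int dz = -1; dz <= 1; ++dz) {
      const int cz = iz + dz;
      if (cz < 0 || cz >= gr.nz) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        const int cy = iy + dy;
        if (cy < 0 || cy >= gr.ny) continue;
        for (int dx = -1; dx <= 1; ++dx) {
          const int cx = ix + dx;
          if (cx < 0 || cx >= gr.nx) continue;
          const int c = gr.cid(cx, cy, cz);
          for (int s = gr.start[c]; s < gr.start[c + 1]; ++s) {
            const int t = gr.items[s];
            closestPtTri(p, Xt + 3 * tpt.T[3 * t], Xt + 3 * tpt.T[3 * t + 1],
                         Xt + 3 * tpt.T[3 * t + 2], q, bc);
            vsub(d, q, p);
            const double r = vnorm(d);
            // ties between equidistant triangles -> lowest triangle index
            if (r < best || (r == best && bestTri >= 0 && t < bestTri)) {
              best = r; bestTri = t;
              vcopy(bestBc, bc);
              if (r > 0) vset(bestDir, d[0] / r, d[1] / r, d[2] / r);
              else vset(bestDir, 0, 0, 0);
            }
          }
        }
      }
    }
    if (bestTri >= 0) {
      cm.tri[i] = bestTri;
      cm.dist[i] = best;
      vcopy(cm.dir.data() + 3 * i, bestDir);
      vcopy(cm.bary.data() + 3 * i, bestBc);
    }
  }
}

// cheap incremental update: refresh distance/direction/barycentrics against
// the cached nearest triangle only (valid while surfaces move by far less
// than the refresh skin between full queries)
static void contactRefreshVTS(const double* Xs, int ns, const double* Xt,
                              const Topo& tpt, double rmax, ContactVTS& cm) {
  double q[3], bc[3], d[3];
  for (int i = 0; i < ns; ++i) {
    const int t = cm.tri[i];
    if (t < 0) continue;
    closestPtTri(Xs + 3 * i, Xt + 3 * tpt.T[3 * t],
                 Xt + 3 * tpt.T[3 * t + 1], Xt + 3 * tpt.T[3 * t + 2], q, bc);
    vsub(d, q, Xs + 3 * i);
    const double r = vnorm(d);
    cm.dist[i] = r;
    vcopy(cm.bary.data() + 3 * i, bc);
    if (r > 0)
      vset(cm.dir.data() + 3 * i, d[0] / r, d[1] / r, d[2] / r);
    (void)rmax;
  }
}

struct ContactVTV {
  std::vector<int> idx;      // nearest target vertex, -1 when none
  std::vector<double> dist;  // rVTV
  std::vector<double> dir;   // 3*nv
};

static void contactQueryVTV(const double* Xs, int ns, const double* Xt,
                            int ntv, double rcutoff, ContactVTV& cm,
                            DenseGrid& gr) {
  cm.idx.assign(ns, -1);
  cm.dist.assign(ns, std::numeric_limits<double>::infinity());
  cm.dir.assign(3 * ns, 0.0);
  buildPointGrid(Xt, ntv, rcutoff, gr);
  double d[3];
  for (int i = 0; i < ns; ++i) {
    const double* p = Xs + 3 * i;
    int ix, iy, iz;
    if (!gr.cellOf(p, ix, iy, iz)) continue;
    double best = rcutoff;
    int bestIdx = -1;
    double bestDir[3] = {0, 0, 0};
    for (int dz = -1; dz <= 1; ++dz) {
      const int cz = iz + dz;
      if (cz < 0 || cz >= gr.nz) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        const int cy = iy + dy;
        if (cy < 0 || cy >= gr.ny) continue;
        for (int dx = -1; dx <= 1; ++dx) {
          const int cx = ix + dx;
          if (cx < 0 || cx >= gr.nx) continue;
          const int c = gr.cid(cx, cy, cz);
          for (int s = gr.start[c]; s < gr.start[c + 1]; ++s) {
            const int j = gr.items[s];
            vsub(d, Xt + 3 * j, p);
            const double r = vnorm(d);
            if (r < best || (r == best && bestIdx >= 0 && j < bestIdx)) {
              best = r; bestIdx = j;
              if (r > 0) vset(bestDir, d[0] / r, d[1] / r, d[2] / r);
            }
          }
        }
      }
    }
    if (bestIdx >= 0) {
      cm.idx[i] = bestIdx;
      cm.dist[i] = best;
      vcopy(cm.dir.data() + 3 * i, bestDir);
    }
  }
}

static void contactRefreshVTV(const double* Xs, int ns, const double* Xt,
                              ContactVTV& cm) {
  double d[3];
  for (int i = 0; i < ns; ++i) {
    const int j = cm.idx[i];
    if (j < 0) continue;
    vsub(d, Xt + 3 * j, Xs + 3 * i);
    const double r = vnorm(d);
    cm.dist[i] = r;
    if (r > 0) vset(cm.dir.data() + 3 * i, d[0] / r, d[1] / r, d[2] / r);
  }
}

// [[Rcpp::export]]
List cpp_contact_vts(NumericMatrix Xs, NumericMatrix Xt, IntegerMatrix Tt,
                     double rcutoff) {
  const int ns = Xs.nrow(), ntv = Xt.nrow();
  Topo tp; tp.nv = ntv; tp.nt = Tt.nrow(); tp.T.resize(3 * tp.nt);
  for (int t = 0; t < tp.nt; ++t)
    for (int k = 0; k < 3; ++k) tp.T[3 * t + k] = Tt(t, k) - 1;
  std::vector<double> xs(3 * ns), xt(3 * ntv);
  for (int i = 0; i < ns; ++i)
    for (int k = 0; k < 3; ++k) xs[3 * i + k] = Xs(i, k);
  for (int i = 0; i < ntv; ++i)
    for (int k = 0; k < 3; ++k) xt[3 * i + k] = Xt(i, k);
  ContactVTS cm;
  DenseGrid gr;
  contactQueryVTS(xs.data(), ns, xt.data(), tp, rcutoff, cm, gr);
  IntegerVector tri(ns);
  NumericVector dist(ns);
  NumericMatrix dir(ns, 3), bary(ns, 3);
  for (int i = 0; i < ns; ++i) {
    tri[i] = cm.tri[i] + 1;  // 0 => no contact
    dist[i] = cm.dist[i];
    for (int k = 0; k < 3; ++k) {
      dir(i, k) = cm.dir[3 * i + k];
      bary(i, k) = cm.bary[3 * i + k];
    }
  }
  return List::create(_["tri"] = tri, _["dist"] = dist, _["dir"] = dir,
                      _["bary"] = bary);
}

// [[Rcpp::export]]
List cpp_contact_vtv(NumericMatrix Xs, NumericMatrix Xt, double rcutoff) {
  const int ns = Xs.nrow(), ntv = Xt.nrow();
  std::vector<double> xs(3 * ns), xt(3 * ntv);
  for (int i = 0; i < ns; ++i)
    for (int k = 0; k < 3; ++k) xs[3 * i + k] = Xs(i, k);
  for (int i = 0; i < ntv; ++i)
    for (int k = 0; k < 3; ++k) xt[3 * i + k] = Xt(i, k);
  ContactVTV cm;
  DenseGrid gr;
  contactQueryVTV(xs.data(), ns, xt.data(), ntv, rcutoff, cm, gr);
  IntegerVector idx(ns);
  NumericVector dist(ns);
  NumericMatrix dir(ns, 3);
  for (int i = 0; i < ns; ++i) {
    idx[i] = cm.idx[i] + 1;
    dist[i] = cm.dist[i];
    for (int k = 0; k < 3; ++k) dir(i, k) = cm.dir[3 * i + k];
  }
  return List::create(_["idx"] = idx, _["dist"] = dist, _["dir"] = dir);
}

// -------------------------------------------------------- membrane mechanics

struct MechParams {
  std::vector<double> kbtp, lmax, kpow;  // per-edge WLC/POW coefficients
  double kb = 0.0, ka = 0.0, kd = 0.0, kv = 0.0;
  double etaT = 0.0, etaC = 0.0, mass = 0.0;
};

static MechParams mechFromList(const List& mech) {
  MechParams mp;
  NumericVector a = mech["spring_kbtp"], b = mech["spring_lmax"],
                c = mech["spring_kpow"];
  mp.kbtp.assign(a.begin(), a.end());
  mp.lmax.assign(b.begin(), b.end());
  mp.kpow.assign(c.begin(), c.end());
  mp.kb = as<double>(mech["kb"]);
  mp.ka = as<double>(mech["ka"]);
  mp.kd = as<double>(mech["kd"]);
  mp.kv = as<double>(mech["kv"]);
  mp.etaT = as<double>(mech["eta_t"]);
  mp.etaC = as<double>(mech["eta_c"]);
  mp.mass = as<double>(mech["mass_vertex"]);
  return mp;
}

// Signed dihedral angle across edge (i,j) with opposite vertices k (in
// triangle (i,j,k)) and l (in triangle (j,i,l)); 0 when flat.
static double dihedralAngle(const double* xi, const double* xj,
                            const double* xk, const double* xl) {
  double e[3], u[3], w[3], n1[3], n2[3];
  vsub(e, xj, xi);
  vsub(u, xk, xi); vcross(n1, e, u);
  vsub(u, xi, xj); vsub(w, xl, xj); vcross(n2, u, w);
  const double ln1 = vnorm(n1), ln2 = vnorm(n2), le = vnorm(e);
  if (ln1 == 0 || ln2 == 0 || le == 0) return 0.0;
  double cx[3]; vcross(cx, n1, n2);
  const double s = vdot(cx, e) / (ln1 * ln2 * le);
  const double c = vdot(n1, n2) / (ln1 * ln2);
  return std::atan2(s, c);
}

static void elasticForces(const double* X, const Topo& tp,
                          const MechParams& mp, const Geom& g, double* F) {
  std::fill(F, F + 3 * tp.nv, 0.0);
  // --- worm-like-chain + power-law edge springs (cytoskeleton shear)
  double d[3];
  for (int e = 0; e < tp.ne; ++e) {
    const int i = tp.E[2 * e], j = tp.E[2 * e + 1];
    vsub(d, X + 3 * j, X + 3 * i);
    const double l = vnorm(d);
    if (l <= 0) continue;
    double x = l / mp.lmax[e];
    if (x > 0.98) x = 0.98;  // WLC divergence guard
    const double om = 1.0 - x;
    const double fwlc = mp.kbtp[e] * (0.25 / (om * om) - 0.25 + x);
    const double fpow = mp.kpow[e] / (l * l);
    const double tension = fwlc - fpow;  // > 0 attracts
    const double s = tension / l;
    for (int k = 0; k < 3; ++k) {
      F[3 * i + k] += s * d[k];
      F[3 * j + k] -= s * d[k];
    }
  }
  // --- dihedral bending
  for (int q = 0; q < tp.nq; ++q) {
    const int i = tp.Q[4 * q], j = tp.Q[4 * q + 1], k = tp.Q[4 * q + 2],
              l = tp.Q[4 * q + 3];
    const double *xi = X + 3 * i, *xj = X + 3 * j, *xk = X + 3 * k,
                 *xl = X + 3 * l;
    double e[3], u[3], w[3], n1[3], n2[3];
    vsub(e, xj, xi);
    vsub(u, xk, xi); vcross(n1, e, u);
    vsub(u, xi, xj); vsub(w, xl, xj); vcross(n2, u, w);
    const double ln1sq = vdot(n1, n1), ln2sq = vdot(n2, n2), le = vnorm(e);
    if (ln1sq == 0 || ln2sq == 0 || le == 0) continue;
    double cx[3]; vcross(cx, n1, n2);
    // sin/cos of the dihedral from the (non-normalized) normals; the
    // angle-difference identity avoids atan2/sin in this hot loop
    const double inv = 1.0 / std::sqrt(ln1sq * ln2sq);
    const double st = vdot(cx, e) * inv / le;
    const double ct = vdot(n1, n2) * inv;
    const double coef = -mp.kb * (st * tp.rest_ct[q] - ct * tp.rest_st[q]);
    // gradient of theta wrt the four vertices (sign fixed by convention
    // theta<0 when k,l fold toward +n); see tests for the FD check
    double ek[3], el[3];
    vsub(ek, xk, xj); vsub(el, xl, xj);
    const double ak = vdot(ek, e) / le, al = vdot(el, e) / le;
    double gk[3], gl[3], gi[3], gj[3];
    for (int m = 0; m < 3; ++m) {
      gk[m] = -le * n1[m] / ln1sq;
      gl[m] = -le * n2[m] / ln2sq;
      gi[m] = -(ak * n1[m] / ln1sq + al * n2[m] / ln2sq);
    }
    // translation invariance: gj = -(gi + gk + gl)
    for (int m = 0; m < 3; ++m) gj[m] = -(gi[m] + gk[m] + gl[m]);
    for (int m = 0; m < 3; ++m) {
      F[3 * i + m] += coef * gi[m];
      F[3 * j + m] += coef * gj[m];
      F[3 * k + m] += coef * gk[m];
      F[3 * l + m] += coef * gl[m];
    }
  }
  // --- global + local area penalties and volume penalty
  const double coefA = mp.ka * (g.area - tp.rest_area) / tp.rest_area;
  const double coefV =
    (tp.rest_vol != 0.0) ? mp.kv * (g.vol - tp.rest_vol) / tp.rest_vol : 0.0;
  double ab[3], n[3], gr[3];
  for (int t = 0; t < tp.nt; ++t) {
    const int ia = tp.T[3 * t], ib = tp.T[3 * t + 1], ic = tp.T[3 * t + 2];
    const double *a = X + 3 * ia, *b = X + 3 * ib, *c = X + 3 * ic;
    double acv[3];
    vsub(ab, b, a); vsub(acv, c, a); vcross(n, ab, acv);
    const double ln = vnorm(n);
    if (ln == 0) continue;
    const double nh[3] = {n[0] / ln, n[1] / ln, n[2] / ln};
    const double coefT =
      coefA + mp.kd * (g.tri_area[t] - tp.rest_tri_area[t]) / tp.rest_tri_area[t];
    // dAt/da = ((b - c) x n_hat) / 2, cyclic for b, c
    const int idx[3] = {ia, ib, ic};
    const double* P[3] = {a, b, c};
    for (int v = 0; v < 3; ++v) {
      double pq[3];
      vsub(pq, P[(v + 1) % 3], P[(v + 2) % 3]);  // (next - prev)
      vcross(gr, pq, nh);
      for (int m = 0; m < 3; ++m) F[3 * idx[v] + m] -= 0.5 * coefT * gr[m];
    }
    // volume gradient: dV/da = (b x c)/6 etc.
    double bc[3], ca[3], abx[3];
    vcross(bc, b, c); vcross(ca, c, a); vcross(abx, a, b);
    for (int m = 0; m < 3; ++m) {
      F[3 * ia + m] -= coefV * bc[m] / 6.0;
      F[3 * ib + m] -= coefV * ca[m] / 6.0;
      F[3 * ic + m] -= coefV * abx[m] / 6.0;
    }
  }
}

static List energyComponents(const double* X, const Topo& tp,
                             const MechParams& mp, const Geom& g) {
  double Ushear = 0.0, Ubend = 0.0, UareaG = 0.0, UareaL = 0.0, Uvol = 0.0;
  double d[3];
  for (int e = 0; e < tp.ne; ++e) {
    const int i = tp.E[2 * e], j = tp.E[2 * e + 1];
    vsub(d, X + 3 * j, X + 3 * i);
    const double l = vnorm(d);
    double x = l / mp.lmax[e];
    if (x > 0.98) x = 0.98;
    // U_wlc = kbtp * lmax * (3x^2 - 2x^3) / (4(1-x));  U_pow = kpow / l
    Ushear += mp.kbtp[e] * mp.lmax[e] * (3 * x * x - 2 * x * x * x) /
                (4.0 * (1.0 - x)) +
              mp.kpow[e] / l;
  }
  for (int q = 0; q < tp.nq; ++q) {
    const double th = dihedralAngle(
      X + 3 * tp.Q[4 * q], X + 3 * tp.Q[4 * q + 1], X + 3 * tp.Q[4 * q + 2],
      X + 3 * tp.Q[4 * q + 3]);
    Ubend += mp.kb * (1.0 - std::cos(th - tp.rest_theta[q]));
  }
  const double dA = g.area - tp.rest_area;
  UareaG = 0.5 * mp.ka * dA * dA / tp.rest_area;
  for (int t = 0; t < tp.nt; ++t) {
    const double dAt = g.tri_area[t] - tp.rest_tri_area[t];
    UareaL += 0.5 * mp.kd * dAt * dAt / tp.rest_tri_area[t];
  }
  if (tp.rest_vol != 0.0) {
    const double dV = g.vol - tp.rest_vol;
    Uvol = 0.5 * mp.kv * dV * dV / tp.rest_vol;
  }
  return List::create(_["shear"] = Ushear, _["bend"] = Ubend,
                      _["area_global"] = UareaG, _["area_local"] = UareaL,
                      _["volume"] = Uvol,
                      _["total"] = Ushear + Ubend + UareaG + UareaL + Uvol);
}

// [[Rcpp::export]]
NumericMatrix cpp_elastic_forces(NumericMatrix V, List mesh, List mech) {
  Topo tp = topoFromList(mesh);
  MechParams mp = mechFromList(mech);
  std::vector<double> X(3 * tp.nv);
  for (int i = 0; i < tp.nv; ++i)
    for (int k = 0; k < 3; ++k) X[3 * i + k] = V(i, k);
  Geom g; computeGeom(X.data(), tp, g);
  std::vector<double> F(3 * tp.nv);
  elasticForces(X.data(), tp, mp, g, F.data());
  NumericMatrix out(tp.nv, 3);
  for (int i = 0; i < tp.nv; ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = F[3 * i + k];
  return out;
}

// [[Rcpp::export]]
List cpp_membrane_energy(NumericMatrix V, List mesh, List mech) {
  Topo tp = topoFromList(mesh);
  MechParams mp = mechFromList(mech);
  std::vector<double> X(3 * tp.nv);
  for (int i = 0; i < tp.nv; ++i)
    for (int k = 0; k < 3; ++k) X[3 * i + k] = V(i, k);
  Geom g; computeGeom(X.data(), tp, g);
  return energyComponents(X.data(), tp, mp, g);
}

static void viscousForces(const double* X, const double* Vel, const Topo& tp,
                          double etaT, double etaC, double* F) {
  std::fill(F, F + 3 * tp.nv, 0.0);
  double d[3], vij[3];
  for (int e = 0; e < tp.ne; ++e) {
    const int i = tp.E[2 * e], j = tp.E[2 * e + 1];
    vsub(d, X + 3 * j, X + 3 * i);
    const double l = vnorm(d);
    if (l <= 0) continue;
    const double eh[3] = {d[0] / l, d[1] / l, d[2] / l};
    vsub(vij, Vel + 3 * i, Vel + 3 * j);
    const double vn = vdot(vij, eh);
    for (int k = 0; k < 3; ++k) {
      const double f = -etaT * vij[k] - etaC * vn * eh[k];
      F[3 * i + k] += f;
      F[3 * j + k] -= f;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_viscous_forces(NumericMatrix V, NumericMatrix Vel,
                                 List mesh, double eta_t, double eta_c) {
  Topo tp = topoFromList(mesh);
  std::vector<double> X(3 * tp.nv), W(3 * tp.nv), F(3 * tp.nv);
  for (int i = 0; i < tp.nv; ++i)
    for (int k = 0; k < 3; ++k) {
      X[3 * i + k] = V(i, k);
      W[3 * i + k] = Vel(i, k);
    }
  viscousForces(X.data(), W.data(), tp, eta_t, eta_c, F.data());
  NumericMatrix out(tp.nv, 3);
  for (int i = 0; i < tp.nv; ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = F[3 * i + k];
  return out;
}

// ------------------------------------------------ adhesion + friction forces

struct AdhParams {
  double gamma_ifgr = 0.0, gamma_ifg = 0.0, gamma_mfg = 0.0;
  double beta = 0.0, r0 = 0.0, rcutoff = 0.0;
  double rglyco = 0.0, mugap = 0.0, eps_gap = 1e-9;
};

static AdhParams adhFromList(const List& p) {
  AdhParams a;
  a.gamma_ifgr = as<double>(p["gamma_ifgr"]);
  a.gamma_ifg = as<double>(p["gamma_ifg"]);
  a.gamma_mfg = as<double>(p["gamma_mfg"]);
  a.beta = as<double>(p["beta"]);
  a.r0 = as<double>(p["r0"]);
  a.rcutoff = as<double>(p["r_cutoff"]);
  a.rglyco = as<double>(p["r_glyco"]);
  a.mugap = as<double>(p["mu_gap"]);
  a.eps_gap = as<double>(p["eps_gap"]);
  return a;
}

// Morse-type force magnitude: Gamma*Ai*(2 beta e^{beta(r0-r)} -
// 2 beta e^{2 beta(r0-r)}), positive = attraction along dir.
static inline double morseForceMag(double gamma, double Ai, double beta,
                                   double r0, double r) {
  const double y = beta * (r0 - r);
  return gamma * Ai * 2.0 * beta * (std::exp(y) - std::exp(2.0 * y));
}

// VTS adhesion (iFgB + mFgB terms) computed per source vertex; reaction
// distributed to the nearest target element by barycentric weights so that
// linear momentum of the pair is conserved exactly.
static void adhesionVTS(const double* Ai, const double* Ns, const double* Nt,
                        const ContactVTS& cm, const Topo& tpt,
                        const AdhParams& ap, int ns, double* Fsrc,
                        double* Ftgt, double* fSumSrc) {
  for (int i = 0; i < ns; ++i) {
    const int t = cm.tri[i];
    if (t < 0) continue;
    const double r = cm.dist[i];
    if (r > ap.rcutoff) continue;
    const int* tv = tpt.T.data() + 3 * t;
    const double* bc = cm.bary.data() + 3 * i;
    double nmfg = 0.0;
    if (ap.gamma_mfg > 0) {
      const double ntInterp =
        bc[0] * Nt[tv[0]] + bc[1] * Nt[tv[1]] + bc[2] * Nt[tv[2]];
      nmfg = Ns[i] + ntInterp;
    }
    const double gamma = ap.gamma_ifg + nmfg * ap.gamma_mfg;
    if (gamma == 0) continue;
    const double mag = morseForceMag(gamma, Ai[i], ap.beta, ap.r0, r);
    const double* dir = cm.dir.data() + 3 * i;
    for (int k = 0; k < 3; ++k) {
      const double f = mag * dir[k];
      Fsrc[3 * i + k] += f;
      if (fSumSrc) fSumSrc[k] += f;
      for (int v = 0; v < 3; ++v) Ftgt[3 * tv[v] + k] -= bc[v] * f;
    }
  }
}

// VTV adhesion (specific iFgRB term); reaction applied to the partner vertex.
static void adhesionVTV(const double* Ai, const ContactVTV& cm,
                        const AdhParams& ap, int ns, double* Fsrc,
                        double* Ftgt, double* fSumSrc) {
  if (ap.gamma_ifgr == 0) return;
  for (int i = 0; i < ns; ++i) {
    const int j = cm.idx[i];
    if (j < 0) continue;
    const double r = cm.dist[i];
    if (r > ap.rcutoff) continue;
    const double mag = morseForceMag(ap.gamma_ifgr, Ai[i], ap.beta, ap.r0, r);
    const double* dir = cm.dir.data() + 3 * i;
    for (int k = 0; k < 3; ++k) {
      const double f = mag * dir[k];
      Fsrc[3 * i + k] += f;
      if (fSumSrc) fSumSrc[k] += f;
      Ftgt[3 * j + k] -= f;
    }
  }
}

// Couette intercellular friction (gap shear stress x Ai): opposes the tangential
// relative velocity between vertex i and the nearest point of the pairing
// surface; applied only within rcutoff of the pairing surface.
static void frictionVTS(const double* Ai, const double* nrmS,
                        const double* VelS, const double* VelT,
                        const ContactVTS& cm, const Topo& tpt,
                        const AdhParams& ap, int ns, double* Fsrc,
                        double* Ftgt) {
  if (ap.mugap == 0) return;
  for (int i = 0; i < ns; ++i) {
    const int t = cm.tri[i];
    if (t < 0) continue;
    const double r = cm.dist[i];
    if (r > ap.rcutoff) continue;
    const int* tv = tpt.T.data() + 3 * t;
    const double* bc = cm.bary.data() + 3 * i;
    double vj[3] = {0, 0, 0};
    for (int v = 0; v < 3; ++v)
      for (int k = 0; k < 3; ++k) vj[k] += bc[v] * VelT[3 * tv[v] + k];
    double vij[3];
    for (int k = 0; k < 3; ++k) vij[k] = VelS[3 * i + k] - vj[k];
    const double* nh = nrmS + 3 * i;
    const double vn = vdot(vij, nh);
    double vt[3];
    for (int k = 0; k < 3; ++k) vt[k] = vij[k] - vn * nh[k];
    double gap = r - 2.0 * ap.rglyco;
    if (gap < ap.eps_gap) gap = ap.eps_gap;
    const double coef = -ap.mugap * Ai[i] / gap;
    for (int k = 0; k < 3; ++k) {
      const double f = coef * vt[k];
      Fsrc[3 * i + k] += f;
      for (int v = 0; v < 3; ++v) Ftgt[3 * tv[v] + k] -= bc[v] * f;
    }
  }
}

// [[Rcpp::export]]
List cpp_adhesion_forces(NumericVector Ai, NumericVector Ns, NumericVector Nt,
                         List vts, List vtv, IntegerMatrix Tt, int nv_tgt,
                         List params) {
  AdhParams ap = adhFromList(params);
  const int ns = Ai.size();
  Topo tpt; tpt.nt = Tt.nrow(); tpt.nv = nv_tgt; tpt.T.resize(3 * tpt.nt);
  for (int t = 0; t < tpt.nt; ++t)
    for (int k = 0; k < 3; ++k) tpt.T[3 * t + k] = Tt(t, k) - 1;
  std::vector<double> Fs(3 * ns, 0.0), Ft(3 * nv_tgt, 0.0);
  double fsum[3] = {0, 0, 0};
  if (vts.size() > 0) {
    ContactVTS cm;
    IntegerVector tri = vts["tri"];
    NumericVector dist = vts["dist"];
    NumericMatrix dir = vts["dir"], bary = vts["bary"];
    cm.tri.resize(ns); cm.dist.resize(ns);
    cm.dir.resize(3 * ns); cm.bary.resize(3 * ns);
    for (int i = 0; i < ns; ++i) {
      cm.tri[i] = tri[i] - 1;
      cm.dist[i] = dist[i];
      for (int k = 0; k < 3; ++k) {
        cm.dir[3 * i + k] = dir(i, k);
        cm.bary[3 * i + k] = bary(i, k);
      }
    }
    adhesionVTS(REAL(Ai), REAL(Ns), REAL(Nt), cm, tpt, ap, ns, Fs.data(),
                Ft.data(), fsum);
  }
  if (vtv.size() > 0) {
    ContactVTV cm;
    IntegerVector idx = vtv["idx"];
    NumericVector dist = vtv["dist"];
    NumericMatrix dir = vtv["dir"];
    cm.idx.resize(ns); cm.dist.resize(ns); cm.dir.resize(3 * ns);
    for (int i = 0; i < ns; ++i) {
      cm.idx[i] = idx[i] - 1;
      cm.dist[i] = dist[i];
      for (int k = 0; k < 3; ++k) cm.dir[3 * i + k] = dir(i, k);
    }
    adhesionVTV(REAL(Ai), cm, ap, ns, Fs.data(), Ft.data(), fsum);
  }
  NumericMatrix Fsrc(ns, 3), Ftgt(nv_tgt, 3);
  for (int i = 0; i < ns; ++i)
    for (int k = 0; k < 3; ++k) Fsrc(i, k) = Fs[3 * i + k];
  for (int i = 0; i < nv_tgt; ++i)
    for (int k = 0; k < 3; ++k) Ftgt(i, k) = Ft[3 * i + k];
  return List::create(_["F_src"] = Fsrc, _["F_tgt"] = Ftgt,
                      _["f_sum_src"] = NumericVector::create(fsum[0], fsum[1],
                                                             fsum[2]));
}

// [[Rcpp::export]]
List cpp_friction_forces(NumericVector Ai, NumericMatrix NrmS,
                         NumericMatrix VelS, NumericMatrix VelT, List vts,
                         IntegerMatrix Tt, int nv_tgt, List params) {
  AdhParams ap = adhFromList(params);
  const int ns = Ai.size();
  Topo tpt; tpt.nt = Tt.nrow(); tpt.nv = nv_tgt; tpt.T.resize(3 * tpt.nt);
  for (int t = 0; t < tpt.nt; ++t)
    for (int k = 0; k < 3; ++k) tpt.T[3 * t + k] = Tt(t, k) - 1;
  ContactVTS cm;
  IntegerVector tri = vts["tri"];
  NumericVector dist = vts["dist"];
  NumericMatrix dir = vts["dir"], bary = vts["bary"];
  cm.tri.resize(ns); cm.dist.resize(ns);
  cm.dir.resize(3 * ns); cm.bary.resize(3 * ns);
  for (int i = 0; i < ns; ++i) {
    cm.tri[i] = tri[i] - 1;
    cm.dist[i] = dist[i];
    for (int k = 0; k < 3; ++k) {
      cm.dir[3 * i + k] = dir(i, k);
      cm.bary[3 * i + k] = bary(i, k);
    }
  }
  std::vector<double> ns_(3 * ns), vs(3 * ns), vt(3 * nv_tgt);
  for (int i = 0; i < ns; ++i)
    for (int k = 0; k < 3; ++k) {
      ns_[3 * i + k] = NrmS(i, k);
      vs[3 * i + k] = VelS(i, k);
    }
  for (int i = 0; i < nv_tgt; ++i)
    for (int k = 0; k < 3; ++k) vt[3 * i + k] = VelT(i, k);
  std::vector<double> Fs(3 * ns, 0.0), Ft(3 * nv_tgt, 0.0);
  frictionVTS(REAL(Ai), ns_.data(), vs.data(), vt.data(), cm, tpt, ap, ns,
              Fs.data(), Ft.data());
  NumericMatrix Fsrc(ns, 3), Ftgt(nv_tgt, 3);
  for (int i = 0; i < ns; ++i)
    for (int k = 0; k < 3; ++k) Fsrc(i, k) = Fs[3 * i + k];
  for (int i = 0; i < nv_tgt; ++i)
    for (int k = 0; k < 3; ++k) Ftgt(i, k) = Ft[3 * i + k];
  return List::create(_["F_src"] = Fsrc, _["F_tgt"] = Ftgt);
}

// --------------------------------------------------------- surface transport

struct TranParams {
  double D = 0.0, delta_fg = 45e-9, phi0 = 1.0, N0 = 1.0;
  bool adsorption = false;
};

static TranParams tranFromList(const List& p) {
  TranParams t;
  t.D = as<double>(p["d_mfg"]);
  t.delta_fg = as<double>(p["delta_fg"]);
  t.phi0 = as<double>(p["phi0"]);
  t.N0 = as<double>(p["n0"]);
  t.adsorption = as<bool>(p["adsorption"]);
  return t;
}

// Drift of adsorbed mobile Fg relative to its adsorption surface,
// projected on the local tangent plane; zero when delta_gap >= delta_fg.
static void driftField(const double* VelS, const double* VelT,
                       const double* nrmS, const ContactVTS& cm,
                       const Topo& tpt, double delta_fg, double rglyco,
                       int ns, double* drift) {
  std::fill(drift, drift + 3 * ns, 0.0);
  for (int i = 0; i < ns; ++i) {
    const int t = cm.tri[i];
    if (t < 0) continue;
    double dgap = cm.dist[i] - 2.0 * rglyco;
    if (dgap >= delta_fg) continue;
    if (dgap < 0) dgap = 0;
    const int* tv = tpt.T.data() + 3 * t;
    const double* bc = cm.bary.data() + 3 * i;
    double vj[3] = {0, 0, 0};
    for (int v = 0; v < 3; ++v)
      for (int k = 0; k < 3; ++k) vj[k] += bc[v] * VelT[3 * tv[v] + k];
    const double w = 0.5 * (delta_fg - dgap) / delta_fg;
    double vd[3];
    for (int k = 0; k < 3; ++k) vd[k] = w * (vj[k] - VelS[3 * i + k]);
    const double* nh = nrmS + 3 * i;
    const double vn = vdot(vd, nh);
    for (int k = 0; k < 3; ++k) drift[3 * i + k] = vd[k] - vn * nh[k];
  }
}

// Adsorption source (Eqs. 6-8): J_constant + J_diffus on exposed surface
// (rsep >= delta_fg, including vertices with no pairing contact), zero in
// tight gaps.
static void adsorptionSource(const double* N, const ContactVTS& cm,
                             const TranParams& tpar, int ns, double* S) {
  const double ell2 = (1.4 * tpar.delta_fg) * (1.4 * tpar.delta_fg);
  const double jconst =
    tpar.D * tpar.N0 * (tpar.phi0 - 1.0) / (tpar.phi0 * ell2);
  for (int i = 0; i < ns; ++i) {
    const double rsep = (cm.tri.empty() || cm.tri[i] < 0)
                          ? std::numeric_limits<double>::infinity()
                          : cm.dist[i];
    if (rsep < tpar.delta_fg) { S[i] = 0.0; continue; }
    const double jdiff =
      -tpar.D * (N[i] * tpar.phi0 - tpar.N0) / (tpar.phi0 * ell2);
    S[i] = jconst + jdiff;
  }
}

// Finite-volume transport update on median-dual control volumes: cotangent
// Laplacian for diffusion, first-order upwind fluxes for drift convection,
// explicit source; operates on the *amount* M_i = N_i * A_i so that the
// total is conserved exactly (fluxes are antisymmetric).
struct TranScratch {
  std::vector<double> w, elen, un, lam, N, dM;
  std::vector<double> grad;        // 3*nv least-squares density gradient
  std::vector<double> nmin, nmax;  // local bounds for the slope limiter
  std::vector<double> qe, outflow; // per-edge fluxes + positivity limiting
};

// weighted least-squares gradient of N over the incident edges, plus local
// min/max over the edge neighbourhood (for monotone slope limiting)
static void densityGradient(const double* X, const Topo& tp,
                            const std::vector<double>& N, TranScratch& sc) {
  const int nv = tp.nv;
  sc.grad.assign(3 * nv, 0.0);
  sc.nmin.assign(nv, 0.0);
  sc.nmax.assign(nv, 0.0);
  for (int i = 0; i < nv; ++i) sc.nmin[i] = sc.nmax[i] = N[i];
  // normal-equation accumulators (symmetric 3x3 per vertex) kept locally in
  // two passes over edges to avoid a per-vertex neighbour list
  std::vector<double> A(6 * nv, 0.0);  // xx, xy, xz, yy, yz, zz
  std::vector<double>& g = sc.grad;
  double d[3];
  for (int e = 0; e < tp.ne; ++e) {
    const int i = tp.E[2 * e], j = tp.E[2 * e + 1];
    vsub(d, X + 3 * j, X + 3 * i);
    const double l2 = vdot(d, d);
    if (l2 <= 0) continue;
    const double wgt = 1.0 / l2;
    const double dn = N[j] - N[i];
    for (int s = 0; s < 2; ++s) {
      const int v = s == 0 ? i : j;
      const double sg = s == 0 ? 1.0 : -1.0;
      A[6 * v] += wgt * d[0] * d[0];
      A[6 * v + 1] += wgt * d[0] * d[1];
      A[6 * v + 2] += wgt * d[0] * d[2];
      A[6 * v + 3] += wgt * d[1] * d[1];
      A[6 * v + 4] += wgt * d[1] * d[2];
      A[6 * v + 5] += wgt * d[2] * d[2];
      g[3 * v] += wgt * sg * dn * d[0];
      g[3 * v + 1] += wgt * sg * dn * d[1];
      g[3 * v + 2] += wgt * sg * dn * d[2];
    }
    sc.nmin[i] = std::min(sc.nmin[i], N[j]);
    sc.nmax[i] = std::max(sc.nmax[i], N[j]);
    sc.nmin[j] = std::min(sc.nmin[j], N[i]);
    sc.nmax[j] = std::max(sc.nmax[j], N[i]);
  }
  for (int v = 0; v < nv; ++v) {
    // solve the 3x3 normal equations (regularized; the surface-tangent
    // system is rank-2, the tiny ridge keeps it well posed)
    double a11 = A[6 * v], a12 = A[6 * v + 1], a13 = A[6 * v + 2];
    double a22 = A[6 * v + 3], a23 = A[6 * v + 4], a33 = A[6 * v + 5];
    const double tr = a11 + a22 + a33;
    const double eps = (tr > 0 ? tr : 1.0) * 1e-8;
    a11 += eps; a22 += eps; a33 += eps;
    const double b1 = g[3 * v], b2 = g[3 * v + 1], b3 = g[3 * v + 2];
    const double det = a11 * (a22 * a33 - a23 * a23) -
                       a12 * (a12 * a33 - a23 * a13) +
                       a13 * (a12 * a23 - a22 * a13);
    if (det == 0) { g[3 * v] = g[3 * v + 1] = g[3 * v + 2] = 0; continue; }
    g[3 * v] = (b1 * (a22 * a33 - a23 * a23) - a12 * (b2 * a33 - a23 * b3) +
                a13 * (b2 * a23 - a22 * b3)) / det;
    g[3 * v + 1] = (a11 * (b2 * a33 - a23 * b3) - b1 * (a12 * a33 - a23 * a13) +
                    a13 * (a12 * b3 - b2 * a13)) / det;
    g[3 * v + 2] = (a11 * (a22 * b3 - b2 * a23) - a12 * (a12 * b3 - b2 * a13) +
                    b1 * (a12 * a23 - a22 * a13)) / det;
  }
}

static void transportStep(const double* X, const Topo& tp, const Geom& g,
                          const double* drift, const double* S, double D,
                          double dt, double* M, TranScratch& sc) {
  const int nv = tp.nv, ne = tp.ne;
  // cotangent weights per edge (clamped at 0 to preserve positivity),
  // accumulated per triangle through the precomputed side->edge table
  std::vector<double>& w = sc.w; w.assign(ne, 0.0);
  std::vector<double>& elen = sc.elen; elen.assign(ne, 0.0);
  for (int e = 0; e < ne; ++e) {
    double d[3];
    vsub(d, X + 3 * tp.E[2 * e + 1], X + 3 * tp.E[2 * e]);
    elen[e] = vnorm(d);
  }
  for (int t = 0; t < tp.nt; ++t) {
    const int tri[3] = {tp.T[3 * t], tp.T[3 * t + 1], tp.T[3 * t + 2]};
    for (int c = 0; c < 3; ++c) {
      const int e = tp.tri_edge[3 * t + c];
      if (e < 0) continue;
      const int a = tri[c], b = tri[(c + 1) % 3], o = tri[(c + 2) % 3];
      double u[3], v[3];
      vsub(u, X + 3 * a, X + 3 * o);
      vsub(v, X + 3 * b, X + 3 * o);
      double cx[3];
      vcross(cx, u, v);
      const double sn = vnorm(cx);
      if (sn <= 0) continue;
      w[e] += 0.5 * vdot(u, v) / sn;
    }
  }
  for (int e = 0; e < ne; ++e)
    if (w[e] < 0) w[e] = 0;
  // densities for flux evaluation
  std::vector<double>& N = sc.N; N.resize(nv);
  for (int i = 0; i < nv; ++i) N[i] = (g.Ai[i] > 0) ? M[i] / g.Ai[i] : 0.0;
  // stability: lambda_i = sum_j (D w_ij + outgoing advective coef) / Ai
  std::vector<double>& lam = sc.lam; lam.assign(nv, 0.0);
  std::vector<double>& un = sc.un; un.assign(ne, 0.0);
  for (int e = 0; e < ne; ++e) {
    const int i = tp.E[2 * e], j = tp.E[2 * e + 1];
    double d[3];
    vsub(d, X + 3 * j, X + 3 * i);
    const double l = elen[e];
    if (l <= 0) continue;
    const double eh[3] = {d[0] / l, d[1] / l, d[2] / l};
    const double uface[3] = {0.5 * (drift[3 * i] + drift[3 * j]),
                             0.5 * (drift[3 * i + 1] + drift[3 * j + 1]),
                             0.5 * (drift[3 * i + 2] + drift[3 * j + 2])};
    un[e] = vdot(uface, eh);  // i -> j face-normal drift speed
    const double lstar = w[e] * l;
    lam[i] += (D * w[e] + std::max(un[e], 0.0) * lstar) / std::max(g.Ai[i], 1e-300);
    lam[j] += (D * w[e] + std::max(-un[e], 0.0) * lstar) / std::max(g.Ai[j], 1e-300);
  }
  double lmax = 0.0;
  for (int i = 0; i < nv; ++i) lmax = std::max(lmax, lam[i]);
  int nsub = 1;
  if (lmax * dt > 0.45) nsub = static_cast<int>(std::ceil(lmax * dt / 0.45));
  const double dts = dt / nsub;
  std::vector<double>& dM = sc.dM; dM.resize(nv);
  const bool second_order = true;
  std::vector<double>& qe = sc.qe; qe.resize(ne);
  std::vector<double>& outflow = sc.outflow; outflow.resize(nv);
  for (int s = 0; s < nsub; ++s) {
    if (second_order) densityGradient(X, tp, N, sc);
    for (int e = 0; e < ne; ++e) {
      const int i = tp.E[2 * e], j = tp.E[2 * e + 1];
      const double lstar = w[e] * elen[e];
      // diffusive amount flux i <- j
      double q = D * w[e] * (N[j] - N[i]);
      // advective flux i -> j: upwind value with a limited second-order
      // reconstruction to the edge midpoint (first-order upwinding alone
      // adds numerical diffusion ~ |u| dx / 2, which would swamp the small
      // physical diffusivity of adsorbed mobile Fg)
      if (un[e] != 0.0) {
        const int u = un[e] > 0 ? i : j;
        double nface = N[u];
        if (second_order) {
          const double* gu = sc.grad.data() + 3 * u;
          double mid[3];
          for (int k = 0; k < 3; ++k)
            mid[k] = 0.5 * (X[3 * i + k] + X[3 * j + k]) - X[3 * u + k];
          nface += vdot(gu, mid);
          // monotone bound: stay within the upwind neighbourhood range
          const double lo = std::min(sc.nmin[u], std::min(N[i], N[j]));
          const double hi = std::max(sc.nmax[u], std::max(N[i], N[j]));
          if (nface < lo) nface = lo;
          if (nface > hi) nface = hi;
          if (nface < 0) nface = 0;
        }
        q -= nface * un[e] * lstar;
      }
      qe[e] = q;  // amount flux into i (negative: out of i)
    }
    // conservative positivity limiting: scale down every flux leaving a
    // control volume that would otherwise be emptied past zero (the
    // second-order reconstruction can raise the face value above the cell
    // mean, so the plain CFL bound alone does not guarantee positivity)
    std::fill(outflow.begin(), outflow.end(), 0.0);
    for (int e = 0; e < ne; ++e) {
      const int i = tp.E[2 * e], j = tp.E[2 * e + 1];
      if (qe[e] < 0) outflow[i] -= qe[e];
      else outflow[j] += qe[e];
    }
    std::fill(dM.begin(), dM.end(), 0.0);
    for (int e = 0; e < ne; ++e) {
      const int i = tp.E[2 * e], j = tp.E[2 * e + 1];
      const int src = qe[e] < 0 ? i : j;
      double q = qe[e];
      const double need = outflow[src] * dts;
      if (need > M[src] && need > 0)
        q *= std::max(0.0, M[src] / need);
      dM[i] += q;
      dM[j] -= q;
    }
    for (int i = 0; i < nv; ++i) {
      M[i] += dts * (dM[i] + S[i] * g.Ai[i]);
      if (M[i] < 0) M[i] = 0;  // defensive; the limiter should prevent this
      N[i] = (g.Ai[i] > 0) ? M[i] / g.Ai[i] : 0.0;
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_transport_step(NumericMatrix V, List mesh, NumericVector N,
                                 NumericMatrix drift, NumericVector source,
                                 double d_mfg, double dt) {
  Topo tp = topoFromList(mesh);
  std::vector<double> X(3 * tp.nv);
  for (int i = 0; i < tp.nv; ++i)
    for (int k = 0; k < 3; ++k) X[3 * i + k] = V(i, k);
  Geom g; computeGeom(X.data(), tp, g);
  std::vector<double> M(tp.nv), dr(3 * tp.nv), S(tp.nv);
  for (int i = 0; i < tp.nv; ++i) {
    M[i] = N[i] * g.Ai[i];
    S[i] = source[i];
    for (int k = 0; k < 3; ++k) dr[3 * i + k] = drift(i, k);
  }
  TranScratch sc;
  transportStep(X.data(), tp, g, dr.data(), S.data(), d_mfg, dt, M.data(), sc);
  NumericVector out(tp.nv);
  for (int i = 0; i < tp.nv; ++i)
    out[i] = (g.Ai[i] > 0) ? M[i] / g.Ai[i] : 0.0;
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_drift_velocity(NumericMatrix VelS, NumericMatrix VelT,
                                 NumericMatrix NrmS, List vts,
                                 IntegerMatrix Tt, double delta_fg,
                                 double r_glyco) {
  const int ns = VelS.nrow();
  Topo tpt; tpt.nt = Tt.nrow(); tpt.T.resize(3 * tpt.nt);
  for (int t = 0; t < tpt.nt; ++t)
    for (int k = 0; k < 3; ++k) tpt.T[3 * t + k] = Tt(t, k) - 1;
  ContactVTS cm;
  IntegerVector tri = vts["tri"];
  NumericVector dist = vts["dist"];
  NumericMatrix bary = vts["bary"];
  cm.tri.resize(ns); cm.dist.resize(ns); cm.bary.resize(3 * ns);
  cm.dir.resize(3 * ns);
  for (int i = 0; i < ns; ++i) {
    cm.tri[i] = tri[i] - 1;
    cm.dist[i] = dist[i];
    for (int k = 0; k < 3; ++k) cm.bary[3 * i + k] = bary(i, k);
  }
  std::vector<double> vs(3 * ns), vt(3 * VelT.nrow()), nr(3 * ns),
    dr(3 * ns, 0.0);
  for (int i = 0; i < ns; ++i)
    for (int k = 0; k < 3; ++k) {
      vs[3 * i + k] = VelS(i, k);
      nr[3 * i + k] = NrmS(i, k);
    }
  for (int i = 0; i < VelT.nrow(); ++i)
    for (int k = 0; k < 3; ++k) vt[3 * i + k] = VelT(i, k);
  driftField(vs.data(), vt.data(), nr.data(), cm, tpt, delta_fg, r_glyco, ns,
             dr.data());
  NumericMatrix out(ns, 3);
  for (int i = 0; i < ns; ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = dr[3 * i + k];
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_adsorption_source(NumericVector N, NumericVector rsep,
                                    List params) {
  TranParams tpar = tranFromList(params);
  const int nv = N.size();
  ContactVTS cm;
  cm.tri.assign(nv, 0);  // mark "has distance"; use rsep directly
  cm.dist.assign(nv, 0.0);
  for (int i = 0; i < nv; ++i) {
    cm.dist[i] = rsep[i];
    if (!R_finite(rsep[i])) cm.tri[i] = -1;
  }
  NumericVector S(nv);
  adsorptionSource(REAL(N), cm, tpar, nv, REAL(S));
  return S;
}

// ------------------------------------------------------------ the simulator

struct BodyRT {
  Topo tp;
  MechParams mp;
  std::vector<double> X, Vel, M;  // positions, velocities, mFg amount
  Geom g;
  std::vector<double> F;       // total force accumulator
  std::vector<double> Fv;      // viscous force scratch
  std::vector<double> adhF;    // adhesion-only force accumulator
  std::vector<double> fricF;   // friction-only force accumulator
  ContactVTS vts;
  ContactVTV vtv;
  DenseGrid triGrid, ptGrid;
};

static double overlapLength(const BodyRT& b1, const BodyRT& b2, int axis) {
  double lo1 = std::numeric_limits<double>::infinity(), hi1 = -lo1;
  double lo2 = lo1, hi2 = -lo1;
  for (int i = 0; i < b1.tp.nv; ++i) {
    lo1 = std::min(lo1, b1.X[3 * i + axis]);
    hi1 = std::max(hi1, b1.X[3 * i + axis]);
  }
  for (int i = 0; i < b2.tp.nv; ++i) {
    lo2 = std::min(lo2, b2.X[3 * i + axis]);
    hi2 = std::max(hi2, b2.X[3 * i + axis]);
  }
  const double ov = std::min(hi1, hi2) - std::max(lo1, lo2);
  return ov > 0 ? ov : 0.0;
}

// area-weighted average gap bridge density N1(i) + N2(nearest) over
// in-contact vertices of both bodies
static double averageGapDensity(const BodyRT& b1, const BodyRT& b2,
                                double rcutoff) {
  double wsum = 0.0, nsum = 0.0;
  const BodyRT* src[2] = {&b1, &b2};
  const BodyRT* tgt[2] = {&b2, &b1};
  for (int s = 0; s < 2; ++s) {
    const BodyRT& S = *src[s];
    const BodyRT& Tg = *tgt[s];
    for (int i = 0; i < S.tp.nv; ++i) {
      const int t = S.vts.tri[i];
      if (t < 0 || S.vts.dist[i] > rcutoff) continue;
      const int* tv = Tg.tp.T.data() + 3 * t;
      const double* bc = S.vts.bary.data() + 3 * i;
      double nt = 0.0;
      for (int v = 0; v < 3; ++v) {
        const double ai = Tg.g.Ai[tv[v]];
        nt += bc[v] * (ai > 0 ? Tg.M[tv[v]] / ai : 0.0);
      }
      const double ni = (S.g.Ai[i] > 0 ? S.M[i] / S.g.Ai[i] : 0.0);
      wsum += S.g.Ai[i];
      nsum += S.g.Ai[i] * (ni + nt);
    }
  }
  return wsum > 0 ? nsum / wsum : NA_REAL;
}

static double contactAreaMetric(const BodyRT& b1, const BodyRT& b2,
                                double rcutoff) {
  double a1 = 0.0, a2 = 0.0;
  for (int i = 0; i < b1.tp.nv; ++i)
    if (b1.vts.tri[i] >= 0 && b1.vts.dist[i] <= rcutoff) a1 += b1.g.Ai[i];
  for (int i = 0; i < b2.tp.nv; ++i)
    if (b2.vts.tri[i] >= 0 && b2.vts.dist[i] <= rcutoff) a2 += b2.g.Ai[i];
  return 0.5 * (a1 + a2);
}

// [[Rcpp::export]]
List cpp_simulate(List mesh1, List mech1, List mesh2, List mech2, List state,
                  List phys, List ctrl) {
  BodyRT b[2];
  b[0].tp = topoFromList(mesh1);
  b[0].mp = mechFromList(mech1);
  b[1].tp = topoFromList(mesh2);
  b[1].mp = mechFromList(mech2);
  {
    NumericMatrix X1 = state["x1"], V1 = state["v1"], X2 = state["x2"],
                  V2 = state["v2"];
    NumericVector N1 = state["n1"], N2 = state["n2"];
    for (int s = 0; s < 2; ++s) {
      NumericMatrix& X = s == 0 ? X1 : X2;
      NumericMatrix& V = s == 0 ? V1 : V2;
      NumericVector& N = s == 0 ? N1 : N2;
      const int nv = b[s].tp.nv;
      b[s].X.resize(3 * nv); b[s].Vel.resize(3 * nv); b[s].M.resize(nv);
      for (int i = 0; i < nv; ++i)
        for (int k = 0; k < 3; ++k) {
          b[s].X[3 * i + k] = X(i, k);
          b[s].Vel[3 * i + k] = V(i, k);
        }
      computeGeom(b[s].X.data(), b[s].tp, b[s].g);
      for (int i = 0; i < nv; ++i) b[s].M[i] = N[i] * b[s].g.Ai[i];
      b[s].F.resize(3 * nv);
      b[s].Fv.resize(3 * nv);
      b[s].adhF.resize(3 * nv);
      b[s].fricF.resize(3 * nv);
    }
  }
  AdhParams ap = adhFromList(phys);
  TranParams tpar = tranFromList(phys);
  // The interface energy density Gamma_affin and the gap Couette stress are
  // interfacial quantities: the simulator samples them from both surfaces
  // and averages, so each side's force assembly carries a factor 1/2.
  AdhParams apHalf = ap;
  apHalf.gamma_ifgr *= 0.5;
  apHalf.gamma_ifg *= 0.5;
  apHalf.gamma_mfg *= 0.5;
  apHalf.mugap *= 0.5;
  const bool transport_on = as<bool>(phys["transport_on"]);
  const bool use_vtv = ap.gamma_ifgr > 0;
  const bool use_vts_adh = (ap.gamma_ifg > 0) || (ap.gamma_mfg > 0);

  const double dt = as<double>(ctrl["dt"]);
  const double t_end = as<double>(ctrl["t_end"]);
  const double settle_t = as<double>(ctrl["settle_t"]);
  const double record_dt = as<double>(ctrl["record_dt"]);
  const double pull_rate = as<double>(ctrl["pull_rate"]);
  const double t_ramp = as<double>(ctrl["t_ramp"]);
  const double escape_f = as<double>(ctrl["escape_f"]);
  const bool stop_on_sep = as<bool>(ctrl["stop_on_sep"]);
  IntegerVector trap1 = ctrl["trap1"], trap2 = ctrl["trap2"];
  std::vector<int> tr[2];
  for (int i = 0; i < trap1.size(); ++i) tr[0].push_back(trap1[i] - 1);
  for (int i = 0; i < trap2.size(); ++i) tr[1].push_back(trap2[i] - 1);
  std::vector<bool> isTrap[2];
  for (int s = 0; s < 2; ++s) {
    isTrap[s].assign(b[s].tp.nv, false);
    for (int i : tr[s]) isTrap[s][i] = true;
  }
  const int nsteps = static_cast<int>(std::ceil(t_end / dt));
  const int rec_every = std::max(1, static_cast<int>(std::round(record_dt / dt)));

  std::vector<std::array<double, 16>> rows;
  rows.reserve(nsteps / rec_every + 2);

  double peak_fot = 0.0, disp_at_peak = 0.0, sep_timer = 0.0;
  bool escaped = false, separated = false;
  double t = 0.0;
  std::vector<double> drift(3 * std::max(b[0].tp.nv, b[1].tp.nv));
  std::vector<double> S(std::max(b[0].tp.nv, b[1].tp.nv));
  std::vector<double> Nd[2];
  TranScratch trsc[2];
  const int tr_every = 8;

  int step = 0;
  for (step = 0; step < nsteps; ++step) {
    t = step * dt;
    // geometry + densities
    for (int s = 0; s < 2; ++s) {
      computeGeom(b[s].X.data(), b[s].tp, b[s].g);
      Nd[s].assign(b[s].tp.nv, 0.0);
      for (int i = 0; i < b[s].tp.nv; ++i)
        Nd[s][i] = b[s].g.Ai[i] > 0 ? b[s].M[i] / b[s].g.Ai[i] : 0.0;
    }
    // contact queries (VTS always: needed for friction/transport/metrics).
    // A full grid query with a skin margin runs every `refresh` steps; in
    // between, distances are re-evaluated against the cached nearest
    // primitive (surfaces move by ~1e-11 m between refreshes, far below
    // the 20 nm skin).
    const bool full_query = (step % 50 == 0);
    const double rquery = ap.rcutoff + 20e-9;
    if (full_query) {
      contactQueryVTS(b[0].X.data(), b[0].tp.nv, b[1].X.data(), b[1].tp,
                      rquery, b[0].vts, b[0].triGrid);
      contactQueryVTS(b[1].X.data(), b[1].tp.nv, b[0].X.data(), b[0].tp,
                      rquery, b[1].vts, b[1].triGrid);
      if (use_vtv) {
        contactQueryVTV(b[0].X.data(), b[0].tp.nv, b[1].X.data(),
                        b[1].tp.nv, rquery, b[0].vtv, b[0].ptGrid);
        contactQueryVTV(b[1].X.data(), b[1].tp.nv, b[0].X.data(),
                        b[0].tp.nv, rquery, b[1].vtv, b[1].ptGrid);
      }
    } else {
      contactRefreshVTS(b[0].X.data(), b[0].tp.nv, b[1].X.data(), b[1].tp,
                        rquery, b[0].vts);
      contactRefreshVTS(b[1].X.data(), b[1].tp.nv, b[0].X.data(), b[0].tp,
                        rquery, b[1].vts);
      if (use_vtv) {
        contactRefreshVTV(b[0].X.data(), b[0].tp.nv, b[1].X.data(), b[0].vtv);
        contactRefreshVTV(b[1].X.data(), b[1].tp.nv, b[0].X.data(), b[1].vtv);
      }
    }
    // forces
    for (int s = 0; s < 2; ++s) {
      elasticForces(b[s].X.data(), b[s].tp, b[s].mp, b[s].g, b[s].F.data());
      viscousForces(b[s].X.data(), b[s].Vel.data(), b[s].tp, b[s].mp.etaT,
                    b[s].mp.etaC, b[s].Fv.data());
      for (int i = 0; i < 3 * b[s].tp.nv; ++i) b[s].F[i] += b[s].Fv[i];
      std::fill(b[s].adhF.begin(), b[s].adhF.end(), 0.0);
      std::fill(b[s].fricF.begin(), b[s].fricF.end(), 0.0);
    }
    for (int s = 0; s < 2; ++s) {
      const int o = 1 - s;
      if (use_vts_adh)
        adhesionVTS(b[s].g.Ai.data(), Nd[s].data(), Nd[o].data(), b[s].vts,
                    b[o].tp, apHalf, b[s].tp.nv, b[s].adhF.data(),
                    b[o].adhF.data(), nullptr);
      if (use_vtv)
        adhesionVTV(b[s].g.Ai.data(), b[s].vtv, apHalf, b[s].tp.nv,
                    b[s].adhF.data(), b[o].adhF.data(), nullptr);
      frictionVTS(b[s].g.Ai.data(), b[s].g.nrm.data(), b[s].Vel.data(),
                  b[o].Vel.data(), b[s].vts, b[o].tp, apHalf, b[s].tp.nv,
                  b[s].fricF.data(), b[o].fricF.data());
    }
    // adhesion / friction force on body 1 along the pulling axis (x)
    double f_agg_x = 0.0, f_fric_x = 0.0;
    for (int i = 0; i < b[0].tp.nv; ++i) {
      f_agg_x += b[0].adhF[3 * i];
      f_fric_x += b[0].fricF[3 * i];
    }
    f_agg_x = std::fabs(f_agg_x);
    for (int s = 0; s < 2; ++s)
      for (int i = 0; i < 3 * b[s].tp.nv; ++i)
        b[s].F[i] += b[s].adhF[i] + b[s].fricF[i];

    // integrate (semi-implicit Euler); kinematic trap on patches.
    // The trap velocity ramps up over t_ramp so the overdamped membrane
    // loads quasi-statically (an instantaneous jump excites a spurious
    // fictitious-mass transient in the reaction force).
    const bool pulling = t >= settle_t;
    const double ramp =
      pulling ? std::min(1.0, (t - settle_t) / t_ramp) : 0.0;
    const double vtrap[2] = {-pull_rate * ramp, pull_rate * ramp};
    double fot[2] = {0.0, 0.0};
    for (int s = 0; s < 2; ++s) {
      const double invm = 1.0 / b[s].mp.mass;
      for (int i = 0; i < b[s].tp.nv; ++i) {
        // during the settle phase the trap patches are held in place
        // (vtrap = 0), letting the contact seat while preserving the
        // prescribed initial overlap
        if (isTrap[s][i]) {
          // quasi-static reaction force needed to enforce the prescribed
          // motion (the fictitious-mass impulse is numerical, not trap load)
          const double rfx = -b[s].F[3 * i];
          fot[s] += rfx;
          b[s].Vel[3 * i] = vtrap[s];
          b[s].Vel[3 * i + 1] = 0.0;
          b[s].Vel[3 * i + 2] = 0.0;
        } else {
          for (int k = 0; k < 3; ++k)
            b[s].Vel[3 * i + k] += b[s].F[3 * i + k] * invm * dt;
        }
        for (int k = 0; k < 3; ++k)
          b[s].X[3 * i + k] += b[s].Vel[3 * i + k] * dt;
      }
    }
    const double f_ot = 0.5 * (std::fabs(fot[0]) + std::fabs(fot[1]));
    const double tau = pulling ? t - settle_t : 0.0;
    const double disp =
      2.0 * pull_rate *
      (tau <= t_ramp ? 0.5 * tau * tau / std::max(t_ramp, 1e-12)
                     : tau - 0.5 * t_ramp);
    if (pulling && !tr[0].empty() && f_ot > peak_fot) {
      peak_fot = f_ot;
      disp_at_peak = disp;
    }

    // transport (operator splitting: advanced every tr_every mechanics
    // steps with the accumulated time increment)
    if (transport_on && (step % tr_every == tr_every - 1)) {
      for (int s = 0; s < 2; ++s) {
        const int o = 1 - s;
        driftField(b[s].Vel.data(), b[o].Vel.data(), b[s].g.nrm.data(),
                   b[s].vts, b[o].tp, tpar.delta_fg, ap.rglyco, b[s].tp.nv,
                   drift.data());
        if (tpar.adsorption)
          adsorptionSource(Nd[s].data(), b[s].vts, tpar, b[s].tp.nv, S.data());
        else
          std::fill(S.begin(), S.begin() + b[s].tp.nv, 0.0);
        transportStep(b[s].X.data(), b[s].tp, b[s].g, drift.data(), S.data(),
                      tpar.D, dt * tr_every, b[s].M.data(), trsc[s]);
      }
    }

    // recording
    if (step % rec_every == 0) {
      int ncontact = 0;
      double min_sep = std::numeric_limits<double>::infinity();
      for (int s = 0; s < 2; ++s)
        for (int i = 0; i < b[s].tp.nv; ++i)
          if (b[s].vts.tri[i] >= 0) {
            ++ncontact;
            min_sep = std::min(min_sep, b[s].vts.dist[i]);
          }
      std::array<double, 16> row;
      row[0] = t;
      row[1] = disp;
      row[2] = f_ot;
      row[3] = f_agg_x;
      row[4] = contactAreaMetric(b[0], b[1], ap.rcutoff);
      row[5] = overlapLength(b[0], b[1], 0);
      row[6] = averageGapDensity(b[0], b[1], ap.rcutoff);
      row[7] = b[0].g.area;
      row[8] = b[0].g.vol;
      row[9] = b[1].g.area;
      row[10] = b[1].g.vol;
      double m1 = 0.0, m2 = 0.0;
      for (int i = 0; i < b[0].tp.nv; ++i) m1 += b[0].M[i];
      for (int i = 0; i < b[1].tp.nv; ++i) m2 += b[1].M[i];
      row[11] = m1;
      row[12] = m2;
      row[13] = R_finite(min_sep) ? min_sep : NA_REAL;
      row[14] = ncontact;
      row[15] = std::fabs(f_fric_x);
      rows.push_back(row);
    }

    // termination checks
    if (pulling && !tr[0].empty() && f_ot >= escape_f) {
      escaped = true;
      ++step;
      break;
    }
    bool any_contact = false;
    for (int s = 0; s < 2 && !any_contact; ++s)
      for (int i = 0; i < b[s].tp.nv; ++i)
        if (b[s].vts.tri[i] >= 0) { any_contact = true; break; }
    if (!any_contact) sep_timer += dt; else sep_timer = 0.0;
    if (stop_on_sep && sep_timer > 0.5) {
      separated = true;
      ++step;
      break;
    }
    if (step % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix traj(rows.size(), 16);
  for (size_t r = 0; r < rows.size(); ++r)
    for (int c = 0; c < 16; ++c) traj(r, c) = rows[r][c];
  colnames(traj) = CharacterVector::create(
    "time", "displacement", "f_ot", "f_agg_x", "contact_area", "overlap",
    "n_ave", "area1", "vol1", "area2", "vol2", "amount1", "amount2",
    "min_sep", "n_contact", "f_fric_x");
  List finals;
  for (int s = 0; s < 2; ++s) {
    const int nv = b[s].tp.nv;
    NumericMatrix X(nv, 3), V(nv, 3);
    NumericVector N(nv);
    computeGeom(b[s].X.data(), b[s].tp, b[s].g);
    for (int i = 0; i < nv; ++i) {
      for (int k = 0; k < 3; ++k) {
        X(i, k) = b[s].X[3 * i + k];
        V(i, k) = b[s].Vel[3 * i + k];
      }
      N[i] = b[s].g.Ai[i] > 0 ? b[s].M[i] / b[s].g.Ai[i] : 0.0;
    }
    finals[s == 0 ? "body1" : "body2"] =
      List::create(_["x"] = X, _["v"] = V, _["n"] = N);
  }
  return List::create(
    _["trajectory"] = traj, _["final"] = finals, _["t_end"] = t,
    _["steps"] = step, _["peak_fot"] = peak_fot,
    _["disp_at_peak"] = disp_at_peak, _["escaped"] = escaped,
    _["separated"] = separated);
}
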