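#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Closest point on triangle (a,b,c) to p; Ericson's region-based algorithm.
// Writes the closest point into out[3].
static inline void closest_pt_triangle(const double *p, const double *a,
                                       const double *b, const double *c,
                                       double *out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    out[0] = a[0]; out[1] = a[1]; out[2] = a[2];
    return;
  }
  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) {
    out[0] = b[0]; out[1] = b[1]; out[2] = b[2];
    return;
  }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }
  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0.0 && d5 <= d6) {
    out[0] = c[0]; out[1] = c[1]; out[2] = c[2];
    return;
  }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

static inline double sqdist3(const double *x, const double *y) {
  double d0 = x[0] - y[0], d1 = x[1] - y[1], d2 = x[2] - y[2];
  return d0 * d0 + d1 * d1 + d2 * d2;
}

struct TriSoup {
  // column-major copies of vertex coordinates per triangle corner
  std::vector<double> A, B, C;
  int nf;
  TriSoup(const NumericMatrix &V, const IntegerMatrix &F) {
    nf = F.nrow();
    A.resize(3 * nf); B.resize(3 * nf); C.resize(3 * nf);
    for (int f = 0; f < nf; ++f) {
      int ia = F(f, 0) - 1, ib = F(f, 1) - 1, ic = F(f, 2) - 1;
      for (int k = 0; k < 3; ++k) {
        A[3 * f + k] = V(ia, k);
        B[3 * f + k] = V(ib, k);
        C[3 * f + k] = V(ic, k);
      }
    }
  }
};

struct Grid {
  int nx, ny, nz;
  double o[3], h[3], hmin;
  std::vector<std::vector<int> > cells;

  int clampi(int v, int lo, int hi) const {
    return v < lo ? lo : (v > hi ? hi : v);
  }
  int cell_of(double x, int axis) const {
    int n = axis == 0 ? nx : (axis == 1 ? ny : nz);
    int c = (int)std::floor((x - o[axis]) / h[axis]);
    return clampi(c, 0, n - 1);
  }
  int idx(int ix, int iy, int iz) const { return (iz * ny + iy) * nx + ix; }

  Grid(const TriSoup &T) {
    double lo[3], hi[3];
    for (int k = 0; k < 3; ++k) { lo[k] = R_PosInf; hi[k] = R_NegInf; }
    for (int f = 0; f < T.nf; ++f) {
      for (int k = 0; k < 3; ++k) {
        lo[k] = std::min(lo[k], std::min(T.A[3 * f + k],
                  std::min(T.B[3 * f + k], T.C[3 * f + k])));
        hi[k] = std::max(hi[k], std::max(T.A[3 * f + k],
                  std::max(T.B[3 * f + k], T.C[3 * f + k])));
      }
    }
    int n = (int)std::ceil(2.0 * std::cbrt((double)std::max(T.nf, 1)));
    n = std::max(2, std::min(n, 96));
    nx = ny = nz = n;
    hmin = R_PosInf;
    for (int k = 0; k < 3; ++k) {
      double ext = hi[k] - lo[k];
      if (ext <= 0) ext = 1e-9;
      o[k] = lo[k] - 1e-9;
      h[k] = (ext + 2e-9) / n;
      hmin = std::min(hmin, h[k]);
    }
    cells.assign((size_t)nx * ny * nz, std::vector<int>());
    for (int f = 0; f < T.nf; ++f) {
      int c0[3], c1[3];
      for (int k = 0; k < 3; ++k) {
        double flo = std::min(T.A[3 * f + k],
                     std::min(T.B[3 * f + k], T.C[3 * f + k]));
        double fhi = std::max(T.A[3 * f + k],
                     std::max(T.B[3 * f + k], T.C[3 * f + k]));
        c0[k] = cell_of(flo, k);
        c1[k] = cell_of(fhi, k);
      }
      for (int iz = c0[2]; iz <= c1[2]; ++iz)
        for (int iy = c0[1]; iy <= c1[1]; ++iy)
          for (int ix = c0[0]; ix <= c1[0]; ++ix)
            cells[idx(ix, iy, iz)].push_back(f);
    }
  }
};

// Exhaustive closest-face scan for one point: lowest face index wins ties.
static inline void brute_query(const TriSoup &T, const double *p,
                               double &best_d2, int &best_f, double *best_pt) {
  best_d2 = R_PosInf;
  best_f = -1;
  double cp[3];
  for (int f = 0; f < T.nf; ++f) {
    closest_pt_triangle(p, &T.A[3 * f], &T.B[3 * f], &T.C[3 * f], cp);
    double d2 = sqdist3(p, cp);
    if (d2 < best_d2) {
      best_d2 = d2;
      best_f = f;
      best_pt[0] = cp[0]; best_pt[1] = cp[1]; best_pt[2] = cp[2];
    }
  }
}

// Grid-accelerated query; identical result to brute_query (index is
// performance-only). Expands Chebyshev shells until the conservative
// bound guarantees no unvisited cell can beat the current best.
static void grid_query(const TriSoup &T, const Grid &G, const double *p,
                       std::vector<int> &stamp, int qid,
                       double &best_d2, int &best_f, double *best_pt) {
  best_d2 = R_PosInf;
  best_f = -1;
  double q[3];  // p clamped into the grid box
  double clamp2 = 0.0;
  for (int k = 0; k < 3; ++k) {
    int n = k == 0 ? G.nx : (k == 1 ? G.ny : G.nz);
    double lo = G.o[k], hi = G.o[k] + n * G.h[k];
    q[k] = std::min(std::max(p[k], lo), hi);
    double d = p[k] - q[k];
    clamp2 += d * d;
  }
  int c[3];
  for (int k = 0; k < 3; ++k) c[k] = G.cell_of(q[k], k);
  int kmax = std::max(G.nx, std::max(G.ny, G.nz));
  double cp[3];
  for (int ring = 0; ring <= kmax; ++ring) {
    // cells at Chebyshev distance ring are at least (ring-1)*hmin away
    if (best_f >= 0 && ring >= 1) {
      double g = (double)(ring - 1) * G.hmin;
      if (best_d2 <= clamp2 + g * g) break;
    }
    int x0 = c[0] - ring, x1 = c[0] + ring;
    int y0 = c[1] - ring, y1 = c[1] + ring;
    int z0 = c[2] - ring, z1 = c[2] + ring;
    for (int iz = z0; iz <= z1; ++iz) {
      if (iz < 0 || iz >= G.nz) continue;
      for (int iy = y0; iy <= y1; ++iy) {
        if (iy < 0 || iy >= G.ny) continue;
        for (int ix = x0; ix <= x1; ++ix) {
          if (ix < 0 || ix >= G.nx) continue;
          // only the shell surface, not the filled cube
          if (ring > 0 && ix != x0 && ix != x1 && iy != y0 && iy != y1 &&
              iz != z0 && iz != z1)
            continue;
          const std::vector<int> &cell = G.cells[G.idx(ix, iy, iz)];
          for (size_t t = 0; t < cell.size(); ++t) {
            int f = cell[t];
            if (stamp[f] == qid) continue;
            stamp[f] = qid;
            closest_pt_triangle(p, &T.A[3 * f], &T.B[3 * f], &T.C[3 * f], cp);
            double d2 = sqdist3(p, cp);
            if (d2 < best_d2 || (d2 == best_d2 && f < best_f)) {
              best_d2 = d2;
              best_f = f;
              best_pt[0] = cp[0]; best_pt[1] = cp[1]; best_pt[2] = cp[2];
            }
          }
        }
      }
    }
  }
}

struct IndexedSurface {
  TriSoup soup;
  Grid grid;
  std::vector<int> stamp;
  int qid;
  IndexedSurface(const NumericMatrix &V, const IntegerMatrix &F)
      : soup(V, F), grid(soup), qid(0) {
    stamp.assign(soup.nf, -1);
  }
};

static List run_queries(const TriSoup &T, Grid *G, std::vector<int> *stamp,
                        int &qid, const NumericMatrix &Q) {
  int nq = Q.nrow();
  NumericVector dist(nq);
  IntegerVector face(nq);
  NumericMatrix pts(nq, 3);
  NumericVector sgn(nq);
  double p[3], bp[3];
  for (int i = 0; i < nq; ++i) {
    p[0] = Q(i, 0); p[1] = Q(i, 1); p[2] = Q(i, 2);
    double d2;
    int f;
    if (G == NULL)
      brute_query(T, p, d2, f, bp);
    else
      grid_query(T, *G, p, *stamp, qid++, d2, f, bp);
    dist[i] = std::sqrt(d2);
    face[i] = f + 1;
    pts(i, 0) = bp[0]; pts(i, 1) = bp[1]; pts(i, 2) = bp[2];
    // sign from the outward normal of the nearest facet
    double e1[3], e2[3], nrm[3];
    for (int k = 0; k < 3; ++k) {
      e1[k] = T.B[3 * f + k] - T.A[3 * f + k];
      e2[k] = T.C[3 * f + k] - T.A[3 * f + k];
    }
    nrm[0] = e1[1] * e2[2] - e1[2] * e2[1];
    nrm[1] = e1[2] * e2[0] - e1[0] * e2[2];
    nrm[2] = e1[0] * e2[1] - e1[1] * e2[0];
    double s = nrm[0] * (p[0] - bp[0]) + nrm[1] * (p[1] - bp[1]) +
               nrm[2] * (p[2] - bp[2]);
    sgn[i] = (s >= 0.0) ? 1.0 : -1.0;
  }
  return List::create(_["distance"] = dist, _["face"] = face,
                      _["point"] = pts, _["sign"] = sgn);
}

// [[Rcpp::export]]
List cpp_closest_on_surface(NumericMatrix Q, NumericMatrix V, IntegerMatrix F,
                            bool brute) {
  TriSoup T(V, F);
  if (brute) {
    int qid = 0;
    return run_queries(T, NULL, NULL, qid, Q);
  }
  Grid G(T);
  std::vector<int> stamp(T.nf, -1);
  int qid = 0;
  return run_queries(T, &G, &stamp, qid, Q);
}

// Build a reusable closest-point index on a fixed target surface.
// [[Rcpp::export]]
SEXP cpp_surface_index(NumericMatrix V, IntegerMatrix F) {
  XPtr<IndexedSurface> xp(new IndexedSurface(V, F), true);
  return xp;
}

// [[Rcpp::export]]
List cpp_index_query(SEXP xp_, NumericMatrix Q) {
  XPtr<IndexedSurface> xp(xp_);
  return run_queries(xp->soup, &xp->grid, &xp->stamp, xp->qid, Q);
}

// Moller-Trumbore ray/triangle intersection; returns t or -1.
static inline double ray_tri(const double *o, const double *d,
                             const double *a, const double *b,
                             const double *c) {
  const double eps = 1e-12;
  double e1[3], e2[3];
  for (int k = 0; k < 3; ++k) { e1[k] = b[k] - a[k]; e2[k] = c[k] - a[k]; }
  double pv[3] = { d[1] * e2[2] - d[2] * e2[1],
                   d[2] * e2[0] - d[0] * e2[2],
                   d[0] * e2[1] - d[1] * e2[0] };
  double det = e1[0] * pv[0] + e1[1] * pv[1] + e1[2] * pv[2];
  if (std::fabs(det) < eps) return -1.0;
  double inv = 1.0 / det;
  double tv[3] = { o[0] - a[0], o[1] - a[1], o[2] - a[2] };
  double u = (tv[0] * pv[0] + tv[1] * pv[1] + tv[2] * pv[2]) * inv;
  if (u < -1e-9 || u > 1.0 + 1e-9) return -1.0;
  double qv[3] = { tv[1] * e1[2] - tv[2] * e1[1],
                   tv[2] * e1[0] - tv[0] * e1[2],
                   tv[0] * e1[1] - tv[1] * e1[0] };
  double v = (d[0] * qv[0] + d[1] * qv[1] + d[2] * qv[2]) * inv;
  if (v < -1e-9 || u + v > 1.0 + 1e-9) return -1.0;
  double t = (e2[0] * qv[0] + e2[1] * qv[1] + e2[2] * qv[2]) * inv;
  return t > eps ? t : -1.0;
}

// Radial ray casting from a common interior origin via 3D-DDA grid
// traversal. Returns, per direction, the largest positive ray parameter
// over all intersected facets (the outermost surface for star-shaped
// meshes), or -1 when the ray misses.
// [[Rcpp::export]]
NumericVector cpp_ray_radial(NumericMatrix D, NumericVector origin,
                             NumericMatrix V, IntegerMatrix F) {
  TriSoup T(V, F);
  Grid G(T);
  std::vector<int> stamp(T.nf, -1);
  int nd = D.nrow();
  NumericVector tmax(nd, -1.0);
  double o[3] = { origin[0], origin[1], origin[2] };
  for (int i = 0; i < nd; ++i) {
    double d[3] = { D(i, 0), D(i, 1), D(i, 2) };
    double best = -1.0;
    // DDA setup: start cell of the origin (clamped into the grid)
    int c[3], nvec[3] = { G.nx, G.ny, G.nz };
    int step[3];
    double tnext[3], tdelta[3];
    for (int k = 0; k < 3; ++k) {
      double x = std::min(std::max(o[k], G.o[k]),
                          G.o[k] + nvec[k] * G.h[k]);
      c[k] = G.cell_of(x, k);
      if (d[k] > 1e-15) {
        step[k] = 1;
        tnext[k] = (G.o[k] + (c[k] + 1) * G.h[k] - o[k]) / d[k];
        tdelta[k] = G.h[k] / d[k];
      } else if (d[k] < -1e-15) {
        step[k] = -1;
        tnext[k] = (G.o[k] + c[k] * G.h[k] - o[k]) / d[k];
        tdelta[k] = -G.h[k] / d[k];
      } else {
        step[k] = 0;
        tnext[k] = R_PosInf;
        tdelta[k] = R_PosInf;
      }
    }
    while (true) {
      const std::vector<int> &cell = G.cells[G.idx(c[0], c[1], c[2])];
      for (size_t t = 0; t < cell.size(); ++t) {
        int f = cell[t];
        if (stamp[f] == i) continue;
        stamp[f] = i;
        double hit = ray_tri(o, d, &T.A[3 * f], &T.B[3 * f], &T.C[3 * f]);
        if (hit > best) best = hit;
      }
      int ax = 0;
      if (tnext[1] < tnext[ax]) ax = 1;
      if (tnext[2] < tnext[ax]) ax = 2;
      if (!R_FINITE(tnext[ax])) break;
      c[ax] += step[ax];
      if (c[ax] < 0 || c[ax] >= nvec[ax]) break;
      tnext[ax] += tdelta[ax];
    }
    tmax[i] = best;
  }
  return tmax;
}
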