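#include "cellsq.h"
using namespace Rcpp;

// column-major accessors (R matrix layout), N = number of nodes
static inline Vec3 get3(const double *p, int i, int N) {
  return Vec3(p[i], p[i + N], p[i + 2 * N]);
}
static inline void add3(double *F, int i, int N, const Vec3 &v) {
  F[i] += v.x; F[i + N] += v.y; F[i + 2 * N] += v.z;
}

// ---- membrane force kernel -------------------------------------------------
// Accumulates all six Kelvin-Voigt membrane contributions into F (3N,
// column-major).  Topology arrays are column-major (as stored by R integer
// matrices, already 0-based).  Degenerate elements are counted and skipped.
int membrane_forces_kernel(const double *pos, const double *vel, int N,
                           const int *tri, int M,
                           const int *edges, const int *edge_tri,
                           const int *edge_opp, int E,
                           const double *L0, const double *theta0,
                           const double *A0, double S0, double V0,
                           double ks, double kb, double kal, double kag, double kV,
                           double kvisc, bool visc_relative, double *F) {
  int n_degen = 0;

  // per-triangle geometry: areas, unit normals, centroids, global area/volume
  static std::vector<double> area, t2sum;
  static std::vector<Vec3> nrm, cen;
  area.resize(M); t2sum.resize(M); nrm.resize(M); cen.resize(M);
  double S = 0.0, V = 0.0;
  for (int t = 0; t < M; ++t) {
    int ia = tri[t], ib = tri[t + M], ic = tri[t + 2 * M];
    Vec3 a = get3(pos, ia, N), b = get3(pos, ib, N), c = get3(pos, ic, N);
    Vec3 nv = cross(b - a, c - a);
    double nn = norm(nv);
    area[t] = 0.5 * nn;
    S += area[t];
    V += dot(cross(a, b), c) / 6.0;
    if (nn < 1e-14) { ++n_degen; nn = 1.0; }
    nrm[t] = (1.0 / nn) * nv;
    cen[t] = (1.0 / 3.0) * (a + b + c);
    Vec3 ta = a - cen[t], tb = b - cen[t], tc = c - cen[t];
    t2sum[t] = dot(ta, ta) + dot(tb, tb) + dot(tc, tc);
  }

  // edge pass: neo-Hookean stretching, membrane viscosity, dihedral bending
  for (int e = 0; e < E; ++e) {
    int ia = edges[e], ib = edges[e + E];
    Vec3 a = get3(pos, ia, N), b = get3(pos, ib, N);
    Vec3 ab = b - a;
    double L = norm(ab);
    if (L < 1e-14) { ++n_degen; continue; }
    Vec3 p = (1.0 / L) * ab;
    if (ks > 0.0) {
      double lam = L / L0[e];
      double mag = ks * kappa_nh(lam) * (L - L0[e]) / L0[e];
      add3(F, ia, N, mag * p);
      add3(F, ib, N, -mag * p);
    }
    if (kvisc > 0.0) {
      Vec3 va = get3(vel, ia, N);
      if (visc_relative) {
        Vec3 vrel = va - get3(vel, ib, N);
        Vec3 fd = (-kvisc * dot(vrel, p)) * p;
        add3(F, ia, N, fd);
        add3(F, ib, N, -1.0 * fd);
      } else {
        // literal damper on the absolute nodal velocity
        add3(F, ia, N, (-kvisc * dot(va, p)) * p);
        Vec3 vb = get3(vel, ib, N);
        add3(F, ib, N, (-kvisc * dot(vb, p)) * p);
      }
    }
    if (kb > 0.0) {
      // restoring loads on the two apex vertices along the triangle
      // normals, compensated on the shared vertices so each hinge is
      // momentum-free
      int t1 = edge_tri[e], t2 = edge_tri[e + E];
      if (area[t1] < 1e-14 || area[t2] < 1e-14) continue;
      int q1 = edge_opp[e], q2 = edge_opp[e + E];
      double th = dihedral_angle(nrm[t1], nrm[t2], a, get3(pos, q2, N));
      double coef = kb * (th - theta0[e]) / theta0[e];
      Vec3 f1 = (-coef) * nrm[t1];
      Vec3 f2 = (-coef) * nrm[t2];
      add3(F, q1, N, f1);
      add3(F, q2, N, f2);
      Vec3 comp = (-0.5) * (f1 + f2);
      add3(F, ia, N, comp);
      add3(F, ib, N, comp);
    }
  }

  // local area, global area, global volume
  if (kal > 0.0 || kag > 0.0 || kV > 0.0) {
    double gA = (S0 > 0.0) ? (S - S0) / S0 : 0.0;
    double gV = (V0 != 0.0) ? (V - V0) / V0 : 0.0;
    for (int t = 0; t < M; ++t) {
      if (area[t] < 1e-14 || t2sum[t] < 1e-14) continue;
      double cl = kal * (area[t] - A0[t]) / t2sum[t];
      double cg = kag * gA * area[t] / t2sum[t];
      Vec3 fv = (-kV * gV * area[t]) * nrm[t];
      for (int k = 0; k < 3; ++k) {
        int iv = tri[t + k * M];
        Vec3 w = get3(pos, iv, N) - cen[t]; // centroid -> vertex
        add3(F, iv, N, (-(cl + cg)) * w);
        add3(F, iv, N, fv);
      }
    }
  }
  return n_degen;
}

// [[Rcpp::export]]
List cpp_membrane_forces(const NumericMatrix &pos, const NumericMatrix &vel,
                         const IntegerMatrix &tri, const IntegerMatrix &edges,
                         const IntegerMatrix &edge_tri, const IntegerMatrix &edge_opp,
                         const NumericVector &L0, const NumericVector &theta0,
                         const NumericVector &A0, double S0, double V0,
                         double ks, double kb, double kal, double kag, double kV,
                         double kvisc, bool visc_relative) {
  int N = pos.nrow();
  NumericMatrix F(N, 3);
  int nd = membrane_forces_kernel(REAL(pos), REAL(vel), N,
                                  INTEGER(tri), tri.nrow(),
                                  INTEGER(edges), INTEGER(edge_tri),
                                  INTEGER(edge_opp), edges.nrow(),
                                  REAL(L0), REAL(theta0), REAL(A0), S0, V0,
                                  ks, kb, kal, kag, kV, kvisc, visc_relative, REAL(F));
  return List::create(_["force"] = F, _["n_degenerate"] = nd);
}

// ---- wall patches ----------------------------------------------------------

// 2D distance from (x, y) to the polyline {pts}, returning foot point
static void polyline_foot(double x, double y, const NumericMatrix &pts,
                          double &dmin, double &fx, double &fy) {
  dmin = R_PosInf; fx = pts(0, 0); fy = pts(0, 1);
  const int K = pts.nrow();
  for (int k = 0; k + 1 < K; ++k) {
    double ax = pts(k, 0), ay = pts(k, 1), bx = pts(k + 1, 0), by = pts(k + 1, 1);
    double vx = bx - ax, vy = by - ay;
    double L2 = vx * vx + vy * vy;
    double t = (L2 > 0.0) ? ((x - ax) * vx + (y - ay) * vy) / L2 : 0.0;
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
    double px = ax + t * vx, py = ay + t * vy;
    double d = std::hypot(x - px, y - py);
    if (d < dmin) { dmin = d; fx = px; fy = py; }
  }
}

// piecewise-linear half-width h(x), clamped outside the profile range
double halfwidth_at(double x, const Rcpp::NumericMatrix &poly) {
  const int K = poly.nrow();
  if (x <= poly(0, 0)) return poly(0, 1);
  if (x >= poly(K - 1, 0)) return poly(K - 1, 1);
  for (int k = 0; k + 1 < K; ++k) {
    if (x <= poly(k + 1, 0)) {
      double t = (x - poly(k, 0)) / (poly(k + 1, 0) - poly(k, 0));
      return poly(k, 1) + t * (poly(k + 1, 1) - poly(k, 1));
    }
  }
  return poly(K - 1, 1);
}

void wall_distance_one(double x, double y, double z,
                       const NumericMatrix &poly,
                       double yc, double zlo, double zhi,
                       double &d_out, Vec3 &m_out) {
  double h = halfwidth_at(x, poly);
  double d_best = R_PosInf;
  Vec3 m_best(0, 0, 0);

  // upper then lower y-wall (mirror); strict < keeps the first patch on ties
  for (int side = 0; side < 2; ++side) {
    double yq = (side == 0) ? y - yc : yc - y; // fold into upper half-plane
    double dmin, fx, fy;
    polyline_foot(x, yq, poly, dmin, fx, fy);
    bool inside = yq < h;
    double d = inside ? dmin : -dmin;
    if (d < d_best) {
      double mx = x - fx, my = yq - fy;
      double nn = std::hypot(mx, my);
      if (nn < 1e-14) { mx = 0.0; my = -1.0; nn = 1.0; }
      mx /= nn; my /= nn;
      if (!inside) { mx = -mx; my = -my; }
      if (side == 1) my = -my; // unfold mirror
      d_best = d; m_best = Vec3(mx, my, 0.0);
    }
  }
  double dz1 = z - zlo;
  if (dz1 < d_best) { d_best = dz1; m_best = Vec3(0, 0, 1); }
  double dz2 = zhi - z;
  if (dz2 < d_best) { d_best = dz2; m_best = Vec3(0, 0, -1); }
  d_out = d_best;
  m_out = m_best;
}

// [[Rcpp::export]]
NumericMatrix cpp_wall_distance(const NumericMatrix &pts, const NumericMatrix &poly,
                                double yc, double zlo, double zhi) {
  const int N = pts.nrow();
  NumericMatrix out(N, 4);
  for (int i = 0; i < N; ++i) {
    double d; Vec3 m;
    wall_distance_one(pts(i, 0), pts(i, 1), pts(i, 2), poly, yc, zlo, zhi, d, m);
    out(i, 0) = d; out(i, 1) = m.x; out(i, 2) = m.y; out(i, 3) = m.z;
  }
  return out;
}

// wall repulsion (power-law, active below d_cut) + kinetic friction
// opposing the nodal velocity.  Returns number of penetration events.
// Far nodes are rejected cheaply: wall slopes are at most 45 degrees, so
// the side-wall distance is at least (h - |y - yc|) / sqrt(2).
int wall_forces_kernel(const double *pos, const double *vel, int N,
                       const NumericMatrix &poly, double yc, double zlo, double zhi,
                       double a, double n_exp, double d_cut, double d_min,
                       double mu_f, double eps_v, bool tangential, double *F) {
  int n_pen = 0;
  if (a <= 0.0) return 0;
  const double inv_sqrt2 = 0.70710678118654752;
  for (int i = 0; i < N; ++i) {
    double x = pos[i], y = pos[i + N], z = pos[i + 2 * N];
    double dy = halfwidth_at(x, poly) - std::fabs(y - yc);
    if (dy * inv_sqrt2 >= d_cut && z - zlo >= d_cut && zhi - z >= d_cut && dy > 0)
      continue;
    double d; Vec3 m;
    wall_distance_one(x, y, z, poly, yc, zlo, zhi, d, m);
    if (d <= 0.0) ++n_pen;
    if (d >= d_cut) continue;
    double de = (d < d_min) ? d_min : d;
    double mag = a * n_exp / std::pow(de, n_exp + 1.0);
    add3(F, i, N, mag * m);
    if (mu_f > 0.0) {
      Vec3 v = get3(vel, i, N);
      if (tangential) v = v - dot(v, m) * m;
      double vn = norm(v);
      if (vn > eps_v) add3(F, i, N, (-mu_f * mag / vn) * v);
    }
  }
  return n_pen;
}

// [[Rcpp::export]]
List cpp_wall_forces(const NumericMatrix &pos, const NumericMatrix &vel,
                     const NumericMatrix &poly, double yc, double zlo, double zhi,
                     double a, double n_exp, double d_cut, double d_min,
                     double mu_f, double eps_v, bool tangential) {
  int N = pos.nrow();
  NumericMatrix F(N, 3);
  int np = wall_forces_kernel(REAL(pos), REAL(vel), N, poly, yc, zlo, zhi,
                              a, n_exp, d_cut, d_min, mu_f, eps_v, tangential, REAL(F));
  return List::create(_["force"] = F, _["n_penetrations"] = np);
}
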