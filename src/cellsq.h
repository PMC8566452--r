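#ifndef CELLSQ_H
#define CELLSQ_H

#include <Rcpp.h>
#include <vector>
#include <cmath>

// small fixed-size 3-vector helpers shared by the geometry, force and
// coupling kernels.  Positions are micrometres, time microseconds, mass
// picograms, so forces come out in nanonewtons.

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
};

inline Vec3 operator+(const Vec3 &a, const Vec3 &b) { return Vec3(a.x + b.x, a.y + b.y, a.z + b.z); }
inline Vec3 operator-(const Vec3 &a, const Vec3 &b) { return Vec3(a.x - b.x, a.y - b.y, a.z - b.z); }
inline Vec3 operator*(double s, const Vec3 &a) { return Vec3(s * a.x, s * a.y, s * a.z); }
inline double dot(const Vec3 &a, const Vec3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return Vec3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
inline double norm(const Vec3 &a) { return std::sqrt(dot(a, a)); }

inline Vec3 row3(const Rcpp::NumericMatrix &m, int i) {
  return Vec3(m(i, 0), m(i, 1), m(i, 2));
}

// neo-Hookean stiffening factor of the edge springs,
// (lam^0.5 + lam^-2.5) / (lam + lam^-3), written in sqrt/div form
inline double kappa_nh(double lam) {
  double s = std::sqrt(lam), l2 = lam * lam;
  return (s + 1.0 / (l2 * s)) / (lam + 1.0 / (l2 * lam));
}

// dihedral angle between the outward-oriented triangles adjacent to an
// edge, measured so a flat pair gives pi and a convex fold < pi.
// n1, n2: unit outward normals; qa: an endpoint of the shared edge;
// q2: the vertex of triangle 2 opposite the edge.
inline double dihedral_angle(const Vec3 &n1, const Vec3 &n2, const Vec3 &qa, const Vec3 &q2) {
  double c = dot(n1, n2);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  double phi = std::acos(c);
  double side = dot(n1, q2 - qa);
  return (side <= 0.0) ? M_PI - phi : M_PI + phi;
}

// signed distance from a point to a width-profile channel wall.
// poly: K x 2 matrix (x, half-width h) describing the upper wall polyline
// y = yc + h(x); the lower wall is its mirror, top/bottom are the planes
// z = zlo and z = zhi.  Returns signed distance (negative = inside solid)
// and the unit wall->fluid direction of the nearest patch; ties go to the
// first patch in the fixed order upper-y, lower-y, z-low, z-high.
void wall_distance_one(double x, double y, double z,
                       const Rcpp::NumericMatrix &poly,
                       double yc, double zlo, double zhi,
                       double &d_out, Vec3 &m_out);

double halfwidth_at(double x, const Rcpp::NumericMatrix &poly);

int membrane_forces_kernel(const double *pos, const double *vel, int N,
                           const int *tri, int M,
                           const int *edges, const int *edge_tri,
                           const int *edge_opp, int E,
                           const double *L0, const double *theta0,
                           const double *A0, double S0, double V0,
                           double ks, double kb, double kal, double kag, double kV,
                           double kvisc, bool visc_relative, double *F);

int wall_forces_kernel(const double *pos, const double *vel, int N,
                       const Rcpp::NumericMatrix &poly, double yc, double zlo, double zhi,
                       double a, double n_exp, double d_cut, double d_min,
                       double mu_f, double eps_v, bool tangential, double *F);

#endif
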