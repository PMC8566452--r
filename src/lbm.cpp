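#include "cellsq.h"
#include "lbm.h"
using namespace Rcpp;

// D3Q19 velocity set, weights and opposite directions
const int E19[19][3] = {
  {0,0,0},
  {1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1},
  {1,1,0},{-1,-1,0},{1,-1,0},{-1,1,0},
  {1,0,1},{-1,0,-1},{1,0,-1},{-1,0,1},
  {0,1,1},{0,-1,-1},{0,1,-1},{0,-1,1}
};
const double W19[19] = {
  1.0/3.0,
  1.0/18.0,1.0/18.0,1.0/18.0,1.0/18.0,1.0/18.0,1.0/18.0,
  1.0/36.0,1.0/36.0,1.0/36.0,1.0/36.0,
  1.0/36.0,1.0/36.0,1.0/36.0,1.0/36.0,
  1.0/36.0,1.0/36.0,1.0/36.0,1.0/36.0
};
const int OPP19[19] = {0, 2,1, 4,3, 6,5, 8,7, 10,9, 12,11, 14,13, 16,15, 18,17};

static inline void eq19(double rho, double ux, double uy, double uz, double *feq) {
  double u2 = ux * ux + uy * uy + uz * uz;
  for (int i = 0; i < 19; ++i) {
    double eu = E19[i][0] * ux + E19[i][1] * uy + E19[i][2] * uz;
    feq[i] = W19[i] * rho * (1.0 + 3.0 * eu + 4.5 * eu * eu - 1.5 * u2);
  }
}

// one BGK collision + halfway bounce-back streaming step (lattice units,
// Guo forcing).  f and fpost are 19 * Nsites arrays (population fastest).
// siteforce may be NULL; it is an extra per-site force density (3 * Nsites,
// component-major: fx at [s], fy at [s + Ns], fz at [s + 2 Ns]).
void lbm_step_once(double *f, double *fpost, const int *solid,
                   int Nx, int Ny, int Nz, double tau,
                   const double *gconst, const double *siteforce,
                   const int *periodic, double *minpop_out) {
  const int Ns = Nx * Ny * Nz;
  const double omega = 1.0 / tau;
  const double fpre = 1.0 - 0.5 * omega;
  double minpop = R_PosInf;
  double feq[19];

  // collision into fpost
  for (int s = 0; s < Ns; ++s) {
    double *fs = f + 19 * s;
    double *fp = fpost + 19 * s;
    if (solid[s]) {
      for (int i = 0; i < 19; ++i) fp[i] = fs[i];
      continue;
    }
    double rho = 0.0, jx = 0.0, jy = 0.0, jz = 0.0;
    for (int i = 0; i < 19; ++i) {
      rho += fs[i];
      jx += fs[i] * E19[i][0];
      jy += fs[i] * E19[i][1];
      jz += fs[i] * E19[i][2];
    }
    double Fx = gconst[0], Fy = gconst[1], Fz = gconst[2];
    if (siteforce) { Fx += siteforce[s]; Fy += siteforce[s + Ns]; Fz += siteforce[s + 2 * Ns]; }
    double ux = (jx + 0.5 * Fx) / rho, uy = (jy + 0.5 * Fy) / rho, uz = (jz + 0.5 * Fz) / rho;
    eq19(rho, ux, uy, uz, feq);
    double uF = ux * Fx + uy * Fy + uz * Fz;
    for (int i = 0; i < 19; ++i) {
      double eF = E19[i][0] * Fx + E19[i][1] * Fy + E19[i][2] * Fz;
      double eu = E19[i][0] * ux + E19[i][1] * uy + E19[i][2] * uz;
      double Si = fpre * W19[i] * (3.0 * (eF - uF) + 9.0 * eu * eF);
      double v = fs[i] - omega * (fs[i] - feq[i]) + Si;
      fp[i] = v;
      if (v < minpop) minpop = v;
    }
  }

  // streaming (pull) with halfway bounce-back at solid links
  for (int z = 0; z < Nz; ++z) for (int y = 0; y < Ny; ++y) for (int x = 0; x < Nx; ++x) {
    int s = x + Nx * (y + Ny * z);
    double *fn = f + 19 * s;
    if (solid[s]) { for (int i = 0; i < 19; ++i) fn[i] = 0.0; continue; }
    for (int i = 0; i < 19; ++i) {
      int sx = x - E19[i][0], sy = y - E19[i][1], sz = z - E19[i][2];
      bool out = false;
      if (sx < 0 || sx >= Nx) { if (periodic[0]) sx = (sx + Nx) % Nx; else out = true; }
      if (sy < 0 || sy >= Ny) { if (periodic[1]) sy = (sy + Ny) % Ny; else out = true; }
      if (sz < 0 || sz >= Nz) { if (periodic[2]) sz = (sz + Nz) % Nz; else out = true; }
      if (out) { fn[i] = fpost[19 * s + OPP19[i]]; continue; }
      int src = sx + Nx * (sy + Ny * sz);
      fn[i] = solid[src] ? fpost[19 * s + OPP19[i]] : fpost[19 * src + i];
    }
  }
  if (minpop_out) *minpop_out = minpop;
}

// trilinear stencil over the 8 lattice sites surrounding a point given in
// lattice coordinates of site centres; solid sites are dropped and the
// remaining weights renormalised.  Returns the number of fluid sites used.
int trilinear_fluid(double xl, double yl, double zl, const int *solid,
                    int Nx, int Ny, int Nz, const int *periodic,
                    int idx[8], double w[8]) {
  int ix = (int)std::floor(xl), iy = (int)std::floor(yl), iz = (int)std::floor(zl);
  double fx = xl - ix, fy = yl - iy, fz = zl - iz;
  int m = 0;
  double tot = 0.0;
  for (int c = 0; c < 8; ++c) {
    int dx = c & 1, dy = (c >> 1) & 1, dz = (c >> 2) & 1;
    int jx = ix + dx, jy = iy + dy, jz = iz + dz;
    if (jx < 0 || jx >= Nx) { if (periodic[0]) jx = (jx % Nx + Nx) % Nx; else continue; }
    if (jy < 0 || jy >= Ny) { if (periodic[1]) jy = (jy % Ny + Ny) % Ny; else continue; }
    if (jz < 0 || jz >= Nz) { if (periodic[2]) jz = (jz % Nz + Nz) % Nz; else continue; }
    int s = jx + Nx * (jy + Ny * jz);
    if (solid[s]) continue;
    double ww = (dx ? fx : 1.0 - fx) * (dy ? fy : 1.0 - fy) * (dz ? fz : 1.0 - fz);
    if (ww <= 0.0) continue;
    idx[m] = s; w[m] = ww; tot += ww; ++m;
  }
  for (int k = 0; k < m; ++k) w[k] /= (tot > 0.0 ? tot : 1.0);
  return m;
}

// ---- exported wrappers -----------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_d3q19_equilibrium(const NumericVector &rho, const NumericMatrix &u) {
  int n = rho.size();
  NumericMatrix out(n, 19);
  double feq[19];
  for (int k = 0; k < n; ++k) {
    eq19(rho[k], u(k, 0), u(k, 1), u(k, 2), feq);
    for (int i = 0; i < 19; ++i) out(k, i) = feq[i];
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_d3q19_velocities() {
  NumericMatrix e(19, 3);
  for (int i = 0; i < 19; ++i) for (int k = 0; k < 3; ++k) e(i, k) = E19[i][k];
  return e;
}

// [[Rcpp::export]]
NumericVector cpp_d3q19_weights() {
  NumericVector w(19);
  for (int i = 0; i < 19; ++i) w[i] = W19[i];
  return w;
}

// [[Rcpp::export]]
double cpp_lbm_steps(NumericVector f, const IntegerVector &solid,
                     const IntegerVector &dims, double tau,
                     const NumericVector &g, Nullable<NumericVector> siteforce,
                     int nsteps, const IntegerVector &periodic) {
  int Nx = dims[0], Ny = dims[1], Nz = dims[2];
  std::vector<double> fpost((size_t)19 * Nx * Ny * Nz);
  const double *sf = NULL;
  NumericVector sfv;
  if (siteforce.isNotNull()) { sfv = siteforce.get(); sf = REAL(sfv); }
  double minpop = R_PosInf, mp;
  for (int it = 0; it < nsteps; ++it) {
    lbm_step_once(REAL(f), fpost.data(), INTEGER(solid), Nx, Ny, Nz, tau,
                  REAL(g), sf, INTEGER(periodic), &mp);
    if (mp < minpop) minpop = mp;
  }
  return minpop;
}

// [[Rcpp::export]]
List cpp_lbm_moments(const NumericVector &f, const IntegerVector &solid,
                     const IntegerVector &dims, const NumericVector &g,
                     Nullable<NumericVector> siteforce) {
  int Ns = dims[0] * dims[1] * dims[2];
  NumericVector rho(Ns);
  NumericMatrix u(Ns, 3);
  const double *sf = NULL;
  NumericVector sfv;
  if (siteforce.isNotNull()) { sfv = siteforce.get(); sf = REAL(sfv); }
  for (int s = 0; s < Ns; ++s) {
    if (solid[s]) { rho[s] = NA_REAL; continue; }
    const double *fs = REAL(f) + 19 * (size_t)s;
    double r = 0, jx = 0, jy = 0, jz = 0;
    for (int i = 0; i < 19; ++i) {
      r += fs[i];
      jx += fs[i] * E19[i][0];
      jy += fs[i] * E19[i][1];
      jz += fs[i] * E19[i][2];
    }
    double Fx = g[0], Fy = g[1], Fz = g[2];
    if (sf) { Fx += sf[s]; Fy += sf[s + Ns]; Fz += sf[s + 2 * Ns]; }
    rho[s] = r;
    u(s, 0) = (jx + 0.5 * Fx) / r;
    u(s, 1) = (jy + 0.5 * Fy) / r;
    u(s, 2) = (jz + 0.5 * Fz) / r;
  }
  return List::create(_["rho"] = rho, _["u"] = u);
}

// [[Rcpp::export]]
NumericMatrix cpp_trilinear(const NumericMatrix &field, const IntegerVector &solid,
                            const IntegerVector &dims, const NumericMatrix &pts_lat,
                            const IntegerVector &periodic) {
  int n = pts_lat.nrow(), Ns = dims[0] * dims[1] * dims[2];
  int nc = field.ncol();
  NumericMatrix out(n, nc);
  int idx[8]; double w[8];
  for (int k = 0; k < n; ++k) {
    int m = trilinear_fluid(pts_lat(k, 0), pts_lat(k, 1), pts_lat(k, 2),
                            INTEGER(solid), dims[0], dims[1], dims[2],
                            INTEGER(periodic), idx, w);
    if (m == 0) { for (int c = 0; c < nc; ++c) out(k, c) = NA_REAL; continue; }
    for (int c = 0; c < nc; ++c) {
      double v = 0.0;
      for (int j = 0; j < m; ++j) v += w[j] * field(idx[j], c);
      out(k, c) = v;
    }
  }
  (void)Ns;
  return out;
}
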