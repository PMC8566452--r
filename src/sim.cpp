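#include "cellsq.h"
#include "lbm.h"
using namespace Rcpp;

static inline Vec3 get3v(const std::vector<double> &p, int i, int N) {
  return Vec3(p[i], p[i + N], p[i + 2 * N]);
}

// moments of one lattice site (raw first moment; the half-force correction
// with the constant driving force is applied by the caller)
static inline void site_moments(const double *fs, double &rho, Vec3 &j) {
  rho = 0.0; j = Vec3(0, 0, 0);
  for (int i = 0; i < 19; ++i) {
    rho += fs[i];
    j.x += fs[i] * E19[i][0];
    j.y += fs[i] * E19[i][1];
    j.z += fs[i] * E19[i][2];
  }
}

// Coupled membrane / fluid time integration of a cell released in a
// force-driven channel (or periodic box).  Lengths in um, time in us,
// mass in pg; the lattice works in its own units with dx (um) and dt_lb
// (us) the grid spacing and fluid time step; the membrane advances with
// step dt and the fluid every n_sub membrane steps.
// [[Rcpp::export]]
List cpp_run_passage(NumericMatrix pos_in, NumericMatrix vel_in,
                     const IntegerMatrix &tri, const IntegerMatrix &edges,
                     const IntegerMatrix &edge_tri, const IntegerMatrix &edge_opp,
                     const NumericVector &L0, const NumericVector &theta0,
                     const NumericVector &A0, double S0, double V0,
                     const NumericVector &par, // named: see R wrapper
                     NumericVector f, const IntegerVector &solid,
                     const IntegerVector &dims, double tau, const NumericVector &g,
                     double dx, double dt_lb, double rho_f,
                     double dt, int n_sub, int max_steps, int record_every,
                     int stall_steps, double stall_eps,
                     bool use_fluid, bool use_walls,
                     const NumericMatrix &poly, double yc, double zlo, double zhi,
                     double x_stop, const IntegerVector &periodic) {
  const int N = pos_in.nrow();
  const int Nx = dims[0], Ny = dims[1], Nz = dims[2];
  const int Ns = Nx * Ny * Nz;

  const double ks = par["ks"], kb = par["kb"], kal = par["kal"], kag = par["kag"],
               kV = par["kV"], kvisc = par["kvisc"];
  const bool visc_rel = par["visc_relative"] > 0.5;
  const double mu_f = par["mu_f"], wall_a = par["wall_a"], wall_n = par["wall_n"],
               d_cut = par["d_cut"], d_min = par["d_min"], eps_v = par["eps_v"];
  const bool tangential = par["tangential"] > 0.5;
  const double xi = par["xi_node"], mass = par["node_mass"];
  const double drag_sign = par["drag_sign"]; // +1: xi (u - v); -1: literal printed sign

  const double C_u = dx / dt_lb;            // lattice -> physical velocity
  const double C_m = rho_f * dx * dx * dx;  // lattice mass unit in pg
  const double C_p = C_m * C_u;             // lattice momentum unit

  std::vector<double> pos(REAL(pos_in), REAL(pos_in) + 3 * N);
  std::vector<double> vel(REAL(vel_in), REAL(vel_in) + 3 * N);
  std::vector<double> F(3 * N, 0.0), acc(3 * N, 0.0);
  std::vector<double> deposit(use_fluid ? 3 * Ns : 0, 0.0);
  std::vector<double> fpost(use_fluid ? (size_t)19 * Ns : 0);

  // per-step memo of site velocities (several nodes share stencil sites)
  std::vector<double> u_site(use_fluid ? 3 * Ns : 0);
  std::vector<int> u_stamp(use_fluid ? Ns : 0, -1);
  int cur_stamp = 0;

  // drag forces and interpolation stencils of the latest force evaluation;
  // each half-kick deposits the matching half-impulse through the same
  // stencil, so the fluid receives exactly the momentum the nodes do
  std::vector<double> drag(use_fluid ? 3 * N : 0, 0.0);
  std::vector<double> st_w(use_fluid ? 8 * N : 0, 0.0);
  std::vector<int> st_idx(use_fluid ? 8 * N : 0, 0);
  std::vector<int> st_m(use_fluid ? N : 0, 0);

  int n_pen = 0, n_record = max_steps / record_every + 2;
  NumericMatrix series(n_record, 8);
  int nrec = 0;
  bool stalled = false, completed = false, blew_up = false;
  double best_trail = -1e300;
  int last_progress = 0;

  // force evaluation at (pos, vel); drag forces and stencils are stored for
  // the half-kick deposits
  auto eval_forces = [&]() {
    std::fill(F.begin(), F.end(), 0.0);
    membrane_forces_kernel(pos.data(), vel.data(), N,
                           INTEGER(tri), tri.nrow(),
                           INTEGER(edges), INTEGER(edge_tri), INTEGER(edge_opp),
                           edges.nrow(),
                           REAL(L0), REAL(theta0), REAL(A0), S0, V0,
                           ks, kb, kal, kag, kV, kvisc, visc_rel, F.data());
    if (use_walls)
      n_pen += wall_forces_kernel(pos.data(), vel.data(), N, poly, yc, zlo, zhi,
                                  wall_a, wall_n, d_cut, d_min, mu_f, eps_v,
                                  tangential, F.data());
    if (use_fluid) {
      ++cur_stamp;
      int idx[8]; double w[8];
      for (int jn = 0; jn < N; ++jn) {
        double xl = pos[jn] / dx - 0.5, yl = pos[jn + N] / dx - 0.5,
               zl = pos[jn + 2 * N] / dx - 0.5;
        int m = trilinear_fluid(xl, yl, zl, INTEGER(solid), Nx, Ny, Nz,
                                INTEGER(periodic), idx, w);
        st_m[jn] = m;
        if (m == 0) { drag[jn] = drag[jn + N] = drag[jn + 2 * N] = 0.0; continue; }
        Vec3 u(0, 0, 0);
        for (int k = 0; k < m; ++k) {
          int s = idx[k];
          if (u_stamp[s] != cur_stamp) {
            double rho; Vec3 jj;
            site_moments(REAL(f) + 19 * (size_t)s, rho, jj);
            u_site[3 * s] = (jj.x + 0.5 * g[0]) / rho;
            u_site[3 * s + 1] = (jj.y + 0.5 * g[1]) / rho;
            u_site[3 * s + 2] = (jj.z + 0.5 * g[2]) / rho;
            u_stamp[s] = cur_stamp;
          }
          u = u + w[k] * Vec3(u_site[3 * s], u_site[3 * s + 1], u_site[3 * s + 2]);
          st_idx[8 * jn + k] = s;
          st_w[8 * jn + k] = w[k];
        }
        u = C_u * u;
        Vec3 v = get3v(vel, jn, N);
        Vec3 Fd = drag_sign * xi * (u - v);
        F[jn] += Fd.x; F[jn + N] += Fd.y; F[jn + 2 * N] += Fd.z;
        drag[jn] = Fd.x; drag[jn + N] = Fd.y; drag[jn + 2 * N] = Fd.z;
      }
    }
  };

  // equal-and-opposite impulse of the stored drag forces onto the fluid
  auto deposit_drag = [&](double impulse_dt) {
    if (!use_fluid) return;
    double sc = -impulse_dt / C_p; // lattice momentum units
    for (int jn = 0; jn < N; ++jn) {
      for (int k = 0; k < st_m[jn]; ++k) {
        int s = st_idx[8 * jn + k];
        double ww = sc * st_w[8 * jn + k];
        deposit[s] += ww * drag[jn];
        deposit[s + Ns] += ww * drag[jn + N];
        deposit[s + 2 * Ns] += ww * drag[jn + 2 * N];
      }
    }
  };

  auto record = [&](double t) {
    if (nrec >= n_record) return;
    double xmin = R_PosInf, xmax = R_NegInf, cx = 0.0, spd = 0.0;
    for (int i = 0; i < N; ++i) {
      double x = pos[i];
      if (x < xmin) xmin = x;
      if (x > xmax) xmax = x;
      cx += x;
      Vec3 v = get3v(vel, i, N);
      spd += norm(v);
    }
    double S = 0.0, V = 0.0;
    for (int t2 = 0; t2 < tri.nrow(); ++t2) {
      Vec3 a = get3v(pos, tri(t2, 0), N), b = get3v(pos, tri(t2, 1), N), c = get3v(pos, tri(t2, 2), N);
      S += 0.5 * norm(cross(b - a, c - a));
      V += dot(cross(a, b), c) / 6.0;
    }
    series(nrec, 0) = t;
    series(nrec, 1) = xmax - xmin;
    series(nrec, 2) = (S - S0) / S0;
    series(nrec, 3) = xmax;
    series(nrec, 4) = xmin;
    series(nrec, 5) = cx / N;
    series(nrec, 6) = spd / N;
    series(nrec, 7) = (V - V0) / V0;
    ++nrec;
  };

  eval_forces(); // initial force
  record(0.0);

  int step = 0;
  for (step = 0; step < max_steps; ++step) {
    if (use_fluid && step % n_sub == 0) {
      lbm_step_once(REAL(f), fpost.data(), INTEGER(solid), Nx, Ny, Nz, tau,
                    REAL(g), deposit.data(), INTEGER(periodic), NULL);
      std::fill(deposit.begin(), deposit.end(), 0.0);
    }
    // velocity Verlet; velocity-dependent terms see the half-step velocity
    for (int i = 0; i < 3 * N; ++i) {
      vel[i] += 0.5 * dt * F[i] / mass;
      pos[i] += dt * vel[i];
    }
    deposit_drag(0.5 * dt);
    eval_forces();
    for (int i = 0; i < 3 * N; ++i) vel[i] += 0.5 * dt * F[i] / mass;
    deposit_drag(0.5 * dt);

    double trail = R_PosInf, lead = R_NegInf;
    for (int i = 0; i < N; ++i) {
      if (pos[i] < trail) trail = pos[i];
      if (pos[i] > lead) lead = pos[i];
    }
    if (!std::isfinite(trail) || !std::isfinite(lead)) { blew_up = true; break; }
    if (trail > best_trail + stall_eps) { best_trail = trail; last_progress = step; }

    if ((step + 1) % record_every == 0) {
      record((step + 1) * dt);
      if (!std::isfinite(pos[0]) || !std::isfinite(trail)) { blew_up = true; break; }
    }
    if (trail > x_stop) { completed = true; record((step + 1) * dt); break; }
    if (stall_steps > 0 && step - last_progress > stall_steps) { stalled = true; break; }
  }

  NumericMatrix pos_out(N, 3), vel_out(N, 3);
  for (int i = 0; i < N; ++i) for (int k = 0; k < 3; ++k) {
    pos_out(i, k) = pos[i + k * N];
    vel_out(i, k) = vel[i + k * N];
  }
  NumericVector dep_sum(3);
  for (int s = 0; s < (use_fluid ? Ns : 0); ++s) {
    dep_sum[0] += deposit[s]; dep_sum[1] += deposit[s + Ns]; dep_sum[2] += deposit[s + 2 * Ns];
  }
  return List::create(_["series"] = series, _["n_record"] = nrec,
                      _["pos"] = pos_out, _["vel"] = vel_out, _["f"] = f,
                      _["stalled"] = stalled, _["completed"] = completed,
                      _["blew_up"] = blew_up, _["n_penetrations"] = n_pen,
                      _["steps"] = step + 1,
                      _["pending_deposit"] = dep_sum);
}

// [[Rcpp::export]]
NumericVector cpp_fluid_momentum(const NumericVector &f, const IntegerVector &solid,
                                 const IntegerVector &dims) {
  int Ns = dims[0] * dims[1] * dims[2];
  NumericVector p(3);
  for (int s = 0; s < Ns; ++s) {
    if (solid[s]) continue;
    const double *fs = REAL(f) + 19 * (size_t)s;
    for (int i = 0; i < 19; ++i) {
      p[0] += fs[i] * E19[i][0];
      p[1] += fs[i] * E19[i][1];
      p[2] += fs[i] * E19[i][2];
    }
  }
  return p;
}

// Quasi-static relaxation of a loaded membrane (no fluid): membrane forces
// plus a constant per-node external load, with an ambient drag -gamma v to
// remove kinetic energy.  Converged when the static residual and nodal
// speeds drop below tolerance.
// [[Rcpp::export]]
List cpp_run_stretch(NumericMatrix pos_in,
                     const IntegerMatrix &tri, const IntegerMatrix &edges,
                     const IntegerMatrix &edge_tri, const IntegerMatrix &edge_opp,
                     const NumericVector &L0, const NumericVector &theta0,
                     const NumericVector &A0, double S0, double V0,
                     double ks, double kb, double kal, double kag, double kV,
                     double kvisc, bool visc_rel,
                     const NumericMatrix &ext, double mass, double gamma,
                     double dt, double tol, double vtol, int check_every, int max_steps) {
  const int N = pos_in.nrow();
  std::vector<double> pos(REAL(pos_in), REAL(pos_in) + 3 * N);
  std::vector<double> vel(3 * N, 0.0), F(3 * N, 0.0);
  std::vector<double> resid_hist;
  bool converged = false;
  double resid = R_PosInf;
  int step = 0;

  auto eval = [&]() {
    std::fill(F.begin(), F.end(), 0.0);
    membrane_forces_kernel(pos.data(), vel.data(), N,
                           INTEGER(tri), tri.nrow(),
                           INTEGER(edges), INTEGER(edge_tri), INTEGER(edge_opp),
                           edges.nrow(),
                           REAL(L0), REAL(theta0), REAL(A0), S0, V0,
                           ks, kb, kal, kag, kV, kvisc, visc_rel, F.data());
    for (int i = 0; i < N; ++i) {
      F[i] += ext(i, 0); F[i + N] += ext(i, 1); F[i + 2 * N] += ext(i, 2);
    }
  };
  auto static_residual = [&]() {
    // residual excludes the artificial ambient drag but includes membrane
    // viscosity at the current (small) velocities
    double r = 0.0, vmax = 0.0;
    for (int i = 0; i < N; ++i) {
      Vec3 fi = get3v(F, i, N), vi = get3v(vel, i, N);
      double nf = norm(fi), nv = norm(vi);
      if (nf > r) r = nf;
      if (nv > vmax) vmax = nv;
    }
    return (vmax > vtol) ? R_PosInf : r;
  };

  eval();
  for (step = 0; step < max_steps; ++step) {
    for (int i = 0; i < 3 * N; ++i) {
      vel[i] += 0.5 * dt * (F[i] - gamma * vel[i]) / mass;
      pos[i] += dt * vel[i];
    }
    eval();
    for (int i = 0; i < 3 * N; ++i) vel[i] += 0.5 * dt * (F[i] - gamma * vel[i]) / mass;
    if ((step + 1) % check_every == 0) {
      resid = static_residual();
      resid_hist.push_back(resid);
      if (!std::isfinite(pos[0])) break;
      if (resid < tol) { converged = true; break; }
    }
  }
  NumericMatrix pos_out(N, 3);
  for (int i = 0; i < N; ++i) for (int k = 0; k < 3; ++k) pos_out(i, k) = pos[i + k * N];
  return List::create(_["pos"] = pos_out, _["converged"] = converged,
                      _["residual"] = resid, _["steps"] = step + 1,
                      _["residual_history"] = NumericVector(resid_hist.begin(), resid_hist.end()));
}
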