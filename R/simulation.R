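#' One velocity-Verlet step
#'
#' Advances node positions and velocities under a force law
#' `force_fn(pos, vel)`. Velocity-dependent forces are evaluated with the
#' half-step velocity, the standard treatment for damped Verlet schemes;
#' with zero force the update preserves uniform motion exactly.
#'
#' @param pos,vel n x 3 matrices (um, um/us)
#' @param force_fn function of `(pos, vel)` returning an n x 3 force (nN)
#' @param dt time step (us)
#' @param mass per-node mass (pg), scalar or length-n
#' @return a list with updated `pos` and `vel`
#' @export
integrate_step <- function(pos, vel, force_fn, dt, mass) {
  a1 <- force_fn(pos, vel) / mass
  vh <- vel + 0.5 * dt * a1
  pos2 <- pos + dt * vh
  a2 <- force_fn(pos2, vh) / mass
  list(pos = pos2, vel = vh + 0.5 * dt * a2)
}

passage_par_vector <- function(params, wall, xi_node, node_mass,
                               viscous_mode, drag_sign) {
  c(ks = params$k_s, kb = params$k_b, kal = params$k_al, kag = params$k_ag,
    kV = params$k_V, kvisc = params$k_visc,
    visc_relative = as.numeric(viscous_mode == "relative"),
    mu_f = wall$mu_f, wall_a = wall$a, wall_n = wall$n_exp,
    d_cut = wall$d_cut, d_min = wall$d_min, eps_v = wall$eps_v,
    tangential = as.numeric(wall$tangential),
    xi_node = xi_node, node_mass = node_mass,
    drag_sign = if (drag_sign == "dissipative") 1 else -1)
}

series_tibble <- function(series, n) {
  s <- series[seq_len(n), , drop = FALSE]
  s <- s[!duplicated(s[, 1]), , drop = FALSE]  # completion may re-record a step
  colnames(s) <- c("t_us", "length_um", "area_strain", "lead_x_um",
                   "trail_x_um", "centroid_x_um", "mean_speed_um_per_us",
                   "volume_dev")
  tibble::as_tibble(s)
}

#' Simulate a cell passing the microfluidic constriction
#'
#' Releases a spring-network cell upstream of the tapered constriction in
#' a pre-converged force-driven flow and integrates the coupled
#' fluid-membrane system until the trailing edge clears the constriction
#' exit (or the cell stalls). Entry time is measured from the leading
#' edge reaching the taper-entrance plane to the trailing edge passing
#' the constriction entrance; transit time from there to the trailing
#' edge passing the exit.
#'
#' @param mesh the cell [trimesh] (rest shape)
#' @param flow_rate driving flow rate (uL/h)
#' @param params [elastic_params] of the membrane
#' @param wall [wall_params] including the surface friction `mu_f`
#' @param geom the [channel_geometry]
#' @param dx,dt,n_sub grid spacing (um), membrane time step (us) and
#'   fluid subcycling factor (the fluid advances every `n_sub` membrane
#'   steps with step `n_sub * dt`)
#' @param visc,rho_f,rho_cell fluid viscosity (mPa s) and densities
#'   (kg/m^3)
#' @param xi_ref coupling reference coefficient; defaults to the
#'   calibration for `visc` via [xi_ref_for_viscosity]
#' @param start_lead_gap gap (um) between the initial leading edge and
#'   the taper-entrance plane
#' @param record_every metric recording interval, in membrane steps
#' @param max_time,stall_time simulated-time budget and no-progress
#'   horizon (us)
#' @param viscous_mode membrane viscosity mode, see [viscous_forces]
#' @param drag_sign coupling sign, see [drag_and_backforce]
#' @param lat optional pre-calibrated steady [fluid_lattice] (reused
#'   across runs at the same flow rate to skip recalibration)
#' @param stop_after stop once the trailing edge clears the constriction
#'   exit (`"exit"`, default) or immediately after complete entry
#'   (`"entry"`, cheaper when only the entry time is needed)
#' @return a `passage_result`: entry/transit times (us), status flags,
#'   the metric time series (tibble), penetration count and final state
#' @export
run_channel_passage <- function(mesh, flow_rate, params = elastic_params(),
                                wall = wall_params(), geom = channel_geometry(),
                                dx = 1, dt = 0.01, n_sub = 10,
                                visc = 0.785, rho_f = 1006, rho_cell = 1050,
                                xi_ref = NULL, start_lead_gap = 1,
                                record_every = 25, max_time = 5e4,
                                stall_time = 500,
                                viscous_mode = c("relative", "literal"),
                                drag_sign = c("dissipative", "literal"),
                                lat = NULL, stop_after = c("exit", "entry")) {
  viscous_mode <- match.arg(viscous_mode)
  drag_sign <- match.arg(drag_sign)
  stop_after <- match.arg(stop_after)
  stopifnot(inherits(mesh, "trimesh"))
  rest <- compute_rest_state(mesh)

  if (is.null(lat)) {
    lat <- fluid_lattice(geom, dx = dx, dt_lb = n_sub * dt, visc = visc,
                         rho_f = rho_f)
    if (flow_rate > 0) lat <- calibrate_driving(lat, flow_rate)
  }

  # place the cell on the centreline, leading edge short of the taper plane
  pos <- mesh$pos
  ctr <- colMeans(pos)
  lead <- max(pos[, 1])
  target <- c(geom$x_taper - start_lead_gap - (lead - ctr[1]),
              geom$yc, (geom$zlo + geom$zhi) / 2)
  pos <- sweep(pos, 2, target - ctr, "+")
  wd <- nearest_wall_distance(pos, geom)
  if (min(wd$d) < wall$d_cut)
    stop("initial cell placement is within d_cut of a wall (min distance ",
         signif(min(wd$d), 3), " um)")

  xi_node <- xi_for_object(mesh$n_nodes, rest$S0,
                           if (is.null(xi_ref)) xi_ref_for_viscosity(visc) else xi_ref)
  node_mass <- rho_cell * 1e-3 * rest$V0 / mesh$n_nodes
  par <- passage_par_vector(params, wall, xi_node, node_mass,
                            viscous_mode, drag_sign)

  out <- cpp_run_passage(pos, matrix(0, mesh$n_nodes, 3),
                         mesh$tri - 1L, mesh$edges - 1L,
                         mesh$edge_tri - 1L, mesh$edge_opp - 1L,
                         rest$L0, rest$theta0, rest$A0, rest$S0, rest$V0,
                         par, lat_dup(lat$f), lat$solid, lat$dims, lat$tau,
                         lat$g, lat$dx, lat$dt_lb, lat$rho_f * 1e-3,
                         dt, as.integer(n_sub), as.integer(ceiling(max_time / dt)),
                         as.integer(record_every),
                         as.integer(ceiling(stall_time / dt)), 1e-2,
                         flow_rate > 0, TRUE,
                         geom$poly, geom$yc, geom$zlo, geom$zhi,
                         if (stop_after == "entry") geom$x_entry + 0.5 else geom$x_exit + 1,
                         lat$periodic)
  if (out$blew_up) stop("numerical blow-up (NaN/Inf) during passage run")

  series <- series_tibble(out$series, out$n_record)
  times <- detect_entry_transit(series, geom$x_taper, geom$x_entry, geom$x_exit)
  structure(list(entry_time = times$entry_time,
                 transit_time = times$transit_time,
                 completed = out$completed, stalled = out$stalled,
                 series = series, n_penetrations = out$n_penetrations,
                 steps = out$steps, flow_rate = flow_rate,
                 params = params, wall = wall, geom = geom,
                 final_pos = out$pos, final_vel = out$vel),
            class = "passage_result")
}

#' @export
print.passage_result <- function(x, ...) {
  cat(sprintf("passage at %g uL/h: ", x$flow_rate))
  if (x$stalled) cat("STALLED after", max(x$series$t_us), "us\n")
  else if (!x$completed) cat("incomplete within the time budget\n")
  else cat(sprintf("entry %.1f us, transit %.1f us\n", x$entry_time, x$transit_time))
  invisible(x)
}

#' Coupled cell-fluid run in a periodic box
#'
#' Integrates a cell immersed in an unbounded (fully periodic, wall-free)
#' fluid initialised at a uniform velocity, the configuration used to
#' check momentum conservation of the dissipative coupling and relaxation
#' of a released cell onto the fluid velocity.
#'
#' @param mesh the cell [trimesh], centred in the box by the caller
#' @param box box edge lengths (um), length 3; must exceed the cell size
#' @param u0 initial uniform fluid velocity (um/us), length 3
#' @param params [elastic_params]
#' @param steps membrane steps to integrate
#' @param dx,dt,n_sub numerics as in [run_channel_passage]
#' @param visc,rho_f,rho_cell fluid and cell properties
#' @param xi_ref coupling reference coefficient
#' @return a list with initial and final total momentum (`p0`, `p1`, pg
#'   um/us; fluid + nodes + pending coupling deposits), the final mean
#'   node velocity `v_mean`, the fluid velocity `u0`, and the node
#'   relaxation time scale `tau_relax` (us)
#' @export
run_coupled_box <- function(mesh, box = c(16, 16, 16), u0 = c(0.1, 0, 0),
                            params = elastic_params(), steps = 2000,
                            dx = 1, dt = 0.01, n_sub = 10,
                            visc = 0.785, rho_f = 1006, rho_cell = 1050,
                            xi_ref = NULL) {
  stopifnot(inherits(mesh, "trimesh"))
  rest <- compute_rest_state(mesh)
  dims <- as.integer(round(box / dx))
  ns <- prod(dims)
  lat <- fluid_lattice(mask = list(solid = rep(0L, ns), dims = dims),
                       dx = dx, dt_lb = n_sub * dt, visc = visc, rho_f = rho_f)
  u0_lat <- lat$units$vel_to_lat(u0)
  lat$f <- as.numeric(t(lbm_equilibrium(rep(1, ns),
                                        matrix(u0_lat, ns, 3, byrow = TRUE))))
  pos <- sweep(mesh$pos, 2, box / 2 - colMeans(mesh$pos), "+")
  xi_node <- xi_for_object(mesh$n_nodes, rest$S0,
                           if (is.null(xi_ref)) xi_ref_for_viscosity(visc) else xi_ref)
  node_mass <- rho_cell * 1e-3 * rest$V0 / mesh$n_nodes
  par <- passage_par_vector(params, wall_params(), xi_node, node_mass,
                            "relative", "dissipative")
  cp <- lat$units$mass * lat$units$vel_from_lat(1)   # lattice momentum in pg um/us
  p_fluid0 <- cpp_fluid_momentum(lat$f, lat$solid, lat$dims) * cp
  out <- cpp_run_passage(pos, matrix(0, mesh$n_nodes, 3),
                         mesh$tri - 1L, mesh$edges - 1L,
                         mesh$edge_tri - 1L, mesh$edge_opp - 1L,
                         rest$L0, rest$theta0, rest$A0, rest$S0, rest$V0,
                         par, lat_dup(lat$f), lat$solid, lat$dims, lat$tau,
                         c(0, 0, 0), lat$dx, lat$dt_lb, lat$rho_f * 1e-3,
                         dt, as.integer(n_sub), as.integer(steps),
                         as.integer(steps), 0L, 1e-2,
                         TRUE, FALSE,
                         matrix(c(0, 1e6), 1), box[2] / 2, -1e6, 1e6,
                         Inf, lat$periodic)
  p_fluid1 <- cpp_fluid_momentum(out$f, lat$solid, lat$dims) * cp +
    out$pending_deposit * cp
  p_nodes1 <- colSums(out$vel) * node_mass
  # final mean fluid velocity: in a periodic box momentum is shared, so the
  # co-moving state sits slightly below the initial fluid velocity
  u_end <- lat$units$vel_from_lat(
    cpp_fluid_momentum(out$f, lat$solid, lat$dims) / sum(out$f))
  list(p0 = p_fluid0, p1 = p_fluid1 + p_nodes1,
       v_mean = colMeans(out$vel), u0 = u0, u_end = u_end,
       tau_relax = node_mass / xi_node,
       momentum_scale = sum(abs(p_fluid0)))
}
#'
#' Applies opposite axial loads to the two polar contact caps of the
#' mesh (the nodes within `contact_fraction` of the axial extent at each
#' end, mimicking the bead contacts of the optical-tweezers experiment)
#' and relaxes the membrane to quasi-static equilibrium at each load.
#' Reports the axial and transverse diameters from the extremal node
#' coordinates.
#'
#' @param mesh the cell [trimesh]
#' @param forces total stretching forces to apply (nN), one row of the
#'   result each
#' @param params [elastic_params]
#' @param contact_fraction fraction of the axial extent defining each
#'   contact cap (in (0, 0.5))
#' @param rho_cell cell density (kg/m^3), sets the nodal mass
#' @param dt integration step (us)
#' @param gamma ambient drag (pg/us) used to reach the static state
#' @param tol residual-force tolerance (nN) for convergence
#' @param vtol nodal-speed tolerance (um/us); must sit above the
#'   integrator's noise floor `~ tol * dt / m`
#' @param max_time time budget per load (us)
#' @return a `stretch_result` tibble with columns `force`, `axial`,
#'   `transverse` (um) and attribute `"converged"` per load
#' @export
run_stretch <- function(mesh, forces, params = elastic_params(),
                        contact_fraction = 0.1, rho_cell = 1050,
                        dt = 0.005, gamma = NULL, tol = 1e-4, vtol = 1e-4,
                        max_time = 2000) {
  stopifnot(inherits(mesh, "trimesh"), length(forces) >= 1,
            contact_fraction > 0, contact_fraction < 0.5)
  rest <- compute_rest_state(mesh)
  pos <- mesh$pos
  ext_ax <- max(pos[, 1]) - min(pos[, 1])
  hi <- which(pos[, 1] >= max(pos[, 1]) - contact_fraction * ext_ax)
  lo <- which(pos[, 1] <= min(pos[, 1]) + contact_fraction * ext_ax)
  node_mass <- rho_cell * 1e-3 * rest$V0 / mesh$n_nodes
  # light ambient damping (relaxation time ~ 2 us) converges faster and with
  # less bias than heavy overdamping
  if (is.null(gamma)) gamma <- 0.5 * node_mass

  res <- lapply(forces, function(FF) {
    ext <- matrix(0, mesh$n_nodes, 3)
    ext[hi, 1] <- FF / length(hi)
    ext[lo, 1] <- -FF / length(lo)
    out <- cpp_run_stretch(pos, mesh$tri - 1L, mesh$edges - 1L,
                           mesh$edge_tri - 1L, mesh$edge_opp - 1L,
                           rest$L0, rest$theta0, rest$A0, rest$S0, rest$V0,
                           params$k_s, params$k_b, params$k_al, params$k_ag,
                           params$k_V, params$k_visc, TRUE,
                           ext, node_mass, gamma, dt, tol, vtol,
                           500L, as.integer(ceiling(max_time / dt)))
    if (!out$converged && FF != 0)
      warning("stretch at F = ", FF, " nN not fully converged (residual ",
              signif(out$residual, 3), " nN)")
    p <- out$pos
    c(axial = max(p[, 1]) - min(p[, 1]),
      transverse = max(p[, 2]) - min(p[, 2]),
      converged = as.numeric(out$converged))
  })
  m <- do.call(rbind, res)
  out <- tibble::tibble(force = forces, axial = m[, "axial"],
                        transverse = m[, "transverse"])
  attr(out, "converged") <- m[, "converged"] > 0
  class(out) <- c("stretch_result", class(out))
  out
}
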