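#' D3Q19 fluid lattice
#'
#' Creates a lattice-Boltzmann fluid initialised at rest equilibrium,
#' either on a voxelised [channel_geometry] or on an explicit solid mask
#' (for box and duct tests). The relaxation time is derived from the fluid
#' properties through [lattice_tau]; the lattice is driven by a constant
#' body force (set by [calibrate_driving]) plus any momentum deposited by
#' an immersed object.
#'
#' @param geom a [channel_geometry], or `NULL` when `mask` is given
#' @param dx grid spacing (um)
#' @param dt_lb fluid time step (us)
#' @param visc dynamic viscosity (mPa s)
#' @param rho_f fluid density (kg/m^3)
#' @param mask optional list with `solid` (integer vector, 1 = wall) and
#'   `dims`; overrides `geom`
#' @param periodic logical length-3, periodicity per axis (non-periodic
#'   domain ends behave as walls)
#' @return a `fluid_lattice` list: populations `f` (19 per site),
#'   `solid`, `dims`, `tau`, grid constants, the body force `g` (lattice
#'   units) and a [unit_map]
#' @export
fluid_lattice <- function(geom = NULL, dx = 1, dt_lb = 0.01, visc = 0.785,
                          rho_f = 1006, mask = NULL,
                          periodic = c(TRUE, TRUE, TRUE)) {
  if (is.null(mask)) {
    stopifnot(inherits(geom, "channel_geometry"))
    mask <- build_channel(geom, dx)
  }
  tau <- lattice_tau(visc, rho_f, dx, dt_lb)
  if (tau <= 0.5) stop("unstable relaxation time tau = ", tau, " <= 0.5")
  ns <- prod(mask$dims)
  f <- rep(cpp_d3q19_weights(), times = ns)   # rho = 1, u = 0 equilibrium
  structure(list(f = f, solid = as.integer(mask$solid), dims = as.integer(mask$dims),
                 tau = tau, dx = dx, dt_lb = dt_lb, visc = visc, rho_f = rho_f,
                 g = c(0, 0, 0), periodic = as.integer(periodic),
                 units = unit_map(dx, dt_lb, rho_f), geom = geom,
                 grid = mask[c("x", "y", "z")]),
            class = "fluid_lattice")
}

#' D3Q19 equilibrium populations
#'
#' Standard second-order LBGK equilibrium. The zeroth moment of the
#' returned populations is `rho` and the first moment `rho * u` exactly.
#'
#' @param rho density (lattice units), length n
#' @param u velocity (lattice units), n x 3
#' @return an n x 19 matrix of populations
#' @export
lbm_equilibrium <- function(rho, u) {
  u <- matrix(u, ncol = 3)
  stopifnot(all(rho > 0), nrow(u) == length(rho))
  if (any(sqrt(rowSums(u^2)) > 0.3))
    warning("velocity above the lattice stability bound of 0.3")
  cpp_d3q19_equilibrium(rho, u)
}

lat_dup <- function(f) { f[1] <- f[1]; f }  # force a private copy

#' Advance the fluid
#'
#' Runs `nsteps` BGK collision + streaming steps with Guo forcing and
#' halfway bounce-back at the solid mask. Errors if any population turns
#' negative (local instability).
#'
#' @param lat a [fluid_lattice]
#' @param nsteps number of fluid steps
#' @param siteforce optional per-site extra force density (lattice units,
#'   numeric of length `3 * prod(dims)`)
#' @return the updated lattice
#' @export
lbm_step <- function(lat, nsteps = 1, siteforce = NULL) {
  f <- lat_dup(lat$f)
  minpop <- cpp_lbm_steps(f, lat$solid, lat$dims, lat$tau, lat$g,
                          siteforce, as.integer(nsteps), lat$periodic)
  if (is.finite(minpop) && minpop < 0)
    stop("negative population (", signif(minpop, 3),
         "): lattice unstable at the current driving/resolution")
  lat$f <- f
  lat
}

#' Macroscopic moments of the lattice
#'
#' Density and velocity fields from the populations, including the
#' half-force correction of the Guo forcing scheme, so `u` is the
#' physically meaningful velocity.
#'
#' @param lat a [fluid_lattice]
#' @param physical if `TRUE`, convert the velocity to um/us
#' @return a list with `rho` (lattice units; `NA` at solid sites) and `u`
#'   (n-sites x 3)
#' @export
lbm_moments <- function(lat, physical = FALSE) {
  out <- cpp_lbm_moments(lat$f, lat$solid, lat$dims, lat$g, NULL)
  if (physical) out$u <- lat$units$vel_from_lat(out$u)
  out
}

#' Volumetric flow rate through a cross-section
#'
#' @param lat a [fluid_lattice]
#' @param i x-index of the cross-section (defaults to mid-domain)
#' @return flow rate in um^3/us
#' @export
lbm_flow_rate <- function(lat, i = NULL) {
  dims <- lat$dims
  if (is.null(i)) i <- max(1L, dims[1] %/% 2L)
  m <- lbm_moments(lat)
  idx <- i + dims[1] * (rep(0:(dims[2] - 1), times = dims[3]) +
                          dims[2] * rep(0:(dims[3] - 1), each = dims[2]))
  ux <- m$u[idx, 1]
  ux[is.na(ux)] <- 0
  sum(ux) * lat$units$vel_from_lat(1) * lat$dx^2
}

#' Run the lattice to steady state
#'
#' Steps the fluid in chunks until the mid-domain flow rate changes by
#' less than `tol` (relative) between consecutive chunks.
#'
#' @param lat a [fluid_lattice]
#' @param chunk fluid steps per convergence check
#' @param tol relative flow-rate change tolerance
#' @param max_chunks iteration cap
#' @return the steady lattice, with attribute `"chunks"`
#' @export
lbm_run_steady <- function(lat, chunk = 200, tol = 1e-4, max_chunks = 400) {
  q_prev <- Inf
  for (k in seq_len(max_chunks)) {
    lat <- lbm_step(lat, chunk)
    q <- lbm_flow_rate(lat)
    if (is.finite(q_prev) && abs(q - q_prev) <= tol * max(abs(q), 1e-300)) {
      attr(lat, "chunks") <- k
      return(lat)
    }
    q_prev <- q
  }
  warning("flow not fully steady after ", max_chunks, " chunks")
  attr(lat, "chunks") <- max_chunks
  lat
}

#' Calibrate the constant driving force to a target flow rate
#'
#' Finds the constant axial body force for which the steady blank-channel
#' flow rate matches `flow_rate` (uL/h). In the Stokes regime the flow
#' responds linearly to the force, so a secant-free proportional update
#' converges in a few rounds. The force is then held constant, mimicking a
#' constant pressure drop.
#'
#' @param lat a blank [fluid_lattice] (no cell)
#' @param flow_rate target volumetric flow rate (uL/h)
#' @param tol relative flow-rate tolerance (default 1%)
#' @param max_iter calibration iteration cap
#' @param g0 initial guess for the lattice body force
#' @return the lattice at the calibrated steady state, with the force in
#'   `$g` and attributes `"flow_rate"` (achieved, uL/h) and `"iterations"`
#' @export
calibrate_driving <- function(lat, flow_rate, tol = 0.01, max_iter = 12,
                              g0 = 1e-6) {
  stopifnot(flow_rate >= 0)
  if (flow_rate == 0) { lat$g <- c(0, 0, 0); return(lat) }
  q_target <- convert_flow_rate(flow_rate, "uL/h")
  g <- g0
  for (it in seq_len(max_iter)) {
    lat$g <- c(g, 0, 0)
    lat <- lbm_run_steady(lat)
    q <- lbm_flow_rate(lat)
    if (abs(q - q_target) <= tol * q_target) {
      attr(lat, "flow_rate") <- convert_flow_rate(q, "um3/us")
      attr(lat, "iterations") <- it
      return(lat)
    }
    if (q <= 0) stop("calibration failed: non-positive flow at g = ", g)
    g <- g * q_target / q
  }
  stop("driving-force calibration did not converge: last relative residual ",
       signif(abs(q - q_target) / q_target, 3))
}

#' Steady velocity profile across the constriction
#'
#' Extracts the steady axial-velocity profile u_x(y) at a cross-section
#' (default mid-constriction, the E-E section) and mid-depth.
#'
#' @param lat a steady [fluid_lattice] built on a channel
#' @param x_pos axial position of the section (um)
#' @return a tibble with `y` (um) and `ux` (um/us)
#' @export
velocity_profile <- function(lat, x_pos = NULL) {
  geom <- lat$geom
  if (is.null(x_pos)) x_pos <- (geom$x_entry + geom$x_exit) / 2
  dims <- lat$dims
  i <- which.min(abs(lat$grid$x - x_pos))
  k <- which.min(abs(lat$grid$z - (geom$zlo + geom$zhi) / 2))
  m <- lbm_moments(lat, physical = TRUE)
  idx <- i + dims[1] * ((seq_len(dims[2]) - 1) + dims[2] * (k - 1))
  tibble::tibble(y = lat$grid$y, ux = ifelse(is.na(m$u[idx, 1]), 0, m$u[idx, 1]))
}

#' Grid-spacing sensitivity study
#'
#' Recomputes the steady blank-channel profile at several grid spacings
#' under the same driving flow rate and reports the pairwise maximum
#' relative deviation at matched transverse positions (relative to the
#' profile peak).
#'
#' @param geom a [channel_geometry]; dimensions whose transverse sizes are
#'   integer multiples of every spacing (the production 30 um / 15 um
#'   sections are, for 1.5/1.25/1 um) voxelise consistently across the
#'   sweep
#' @param dxs grid spacings to compare (um)
#' @param flow_rate driving flow rate (uL/h)
#' @param dt_lb fluid time step for dx = 1 (scaled diffusively as
#'   `dt_lb * dx^2` for the other spacings)
#' @param x_pos axial position of the compared cross-section (um);
#'   defaults to the middle of the upstream wide section
#' @param ... passed to [fluid_lattice]
#' @return a list with `profiles` (tibble: dx, y, ux) and
#'   `max_rel_deviation` over all pairs
#' @export
grid_study <- function(geom, dxs = c(1.5, 1.25, 1), flow_rate = 45.6,
                       dt_lb = 0.1, x_pos = NULL, ...) {
  if (is.null(x_pos)) x_pos <- geom$x_taper / 2
  profs <- lapply(dxs, function(dx) {
    lat <- fluid_lattice(geom, dx = dx, dt_lb = dt_lb * dx^2, ...)
    lat <- calibrate_driving(lat, flow_rate)
    cbind(dx = dx, velocity_profile(lat, x_pos = x_pos))
  })
  # compare on the coarsest grid's interior fluid points
  ref_y <- profs[[1]]$y[profs[[1]]$ux != 0]
  vals <- vapply(profs, function(p) stats::approx(p$y, p$ux, xout = ref_y, rule = 2)$y,
                 numeric(length(ref_y)))
  peak <- max(abs(vals))
  dev <- 0
  for (a in seq_along(dxs)) for (b in seq_along(dxs)) if (a < b)
    dev <- max(dev, max(abs(vals[, a] - vals[, b])) / peak)
  list(profiles = tibble::as_tibble(do.call(rbind, profs)),
       max_rel_deviation = dev)
}
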