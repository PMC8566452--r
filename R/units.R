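#' Simulation unit system
#'
#' The package works in a micrometre--microsecond--picogram unit system.
#' This choice makes every printed physical constant map onto a simulation
#' value with no numeric change: forces come out in nanonewtons
#' (pg um / us^2 = 1e-9 N), dynamic viscosity in mPa s
#' (pg / (um us) = 1e-3 Pa s) and fluid/membrane coupling coefficients in
#' nN s/m (pg / us). Densities in kg/m^3 convert by a factor 1e-3 to
#' pg/um^3. The viscoelastic moduli of the spring-network model are taken
#' as given in this system.
#'
#' @param dx lattice grid spacing (um)
#' @param dt_lb fluid time step (us)
#' @param rho_f fluid density (kg/m^3)
#' @return an object of class `unit_map`: a list of conversion closures
#'   between physical (um, us, pg) and lattice quantities, with fields
#'   `dx`, `dt`, `mass` (lattice mass unit in pg) plus `vel_to_lat`,
#'   `vel_from_lat`, `len_to_lat`, `len_from_lat`, `force_density_to_lat`,
#'   `flow_to_lat` and `flow_from_lat`.
#' @details Lattice density 1 corresponds to the physical fluid density,
#'   so the lattice mass unit is `rho_f * dx^3` (in pg after the kg/m^3 ->
#'   pg/um^3 conversion). Round-tripping any quantity through the map is
#'   the identity to machine precision.
#' @export
unit_map <- function(dx = 1, dt_lb = 0.01, rho_f = 1006) {
  rho_pg <- rho_f * 1e-3          # pg / um^3
  mass <- rho_pg * dx^3           # lattice mass unit in pg
  cu <- dx / dt_lb                # lattice -> physical velocity
  structure(list(
    dx = dx, dt = dt_lb, mass = mass, rho_pg = rho_pg,
    len_to_lat = function(x) x / dx,
    len_from_lat = function(x) x * dx,
    vel_to_lat = function(u) u / cu,
    vel_from_lat = function(u) u * cu,
    # force density pg/(um^2 us^2) -> lattice (mass dx / dt^2 per dx^3)
    force_density_to_lat = function(f) f * dx^2 * dt_lb^2 / mass * dx,
    # volumetric flow rate um^3/us -> lattice
    flow_to_lat = function(q) q * dt_lb / dx^3,
    flow_from_lat = function(q) q * dx^3 / dt_lb
  ), class = "unit_map")
}

#' Relaxation time from fluid properties
#'
#' Derives the BGK relaxation time from the lattice kinematic viscosity
#' relation `nu_lattice = c_s^2 (tau - 1/2)` with `c_s^2 = 1/3`.
#'
#' @param visc dynamic viscosity (mPa s)
#' @param rho_f fluid density (kg/m^3)
#' @param dx grid spacing (um)
#' @param dt_lb fluid time step (us)
#' @return the relaxation time `tau` (lattice units)
#' @export
lattice_tau <- function(visc = 0.785, rho_f = 1006, dx = 1, dt_lb = 0.01) {
  nu_phys <- visc / (rho_f * 1e-3)   # kinematic, um^2/us
  nu_lat <- nu_phys * dt_lb / dx^2
  3 * nu_lat + 0.5
}

#' Convert a flow rate between uL/h and um^3/us
#'
#' @param q flow rate
#' @param from unit of `q`, `"uL/h"` or `"um3/us"`
#' @return the converted flow rate
#' @export
convert_flow_rate <- function(q, from = c("uL/h", "um3/us")) {
  from <- match.arg(from)
  if (from == "uL/h") q / 3.6 else q * 3.6
}

#' Flow rates from Poiseuille pressure scaling
#'
#' In the Stokes regime the volumetric flow rate of the blank medium scales
#' linearly with the driving pressure drop, so a single reference
#' measurement fixes the flow rate at any other pressure.
#'
#' @param pressure pressure drops (psi) at which flow rates are wanted
#' @param q_ref reference flow rate (uL/h) of the blank medium
#' @param p_ref pressure drop (psi) of the reference measurement
#' @return flow rates (uL/h) at `pressure`
#' @examples
#' poiseuille_flow_rates(c(0.9, 1.8)) # 22.8 and 45.6 uL/h
#' @export
poiseuille_flow_rates <- function(pressure, q_ref = 38, p_ref = 1.5) {
  stopifnot(q_ref > 0, p_ref > 0, all(pressure >= 0))
  q_ref * pressure / p_ref
}
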