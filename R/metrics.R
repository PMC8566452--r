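#' Scalar observables of a cell configuration
#'
#' Cell length (axial extent over nodes), leading/trailing edge
#' x-positions, centroid and area strain relative to the rest shape. No
#' smoothing or averaging is applied.
#'
#' @param mesh a [trimesh]
#' @param rest its [compute_rest_state]
#' @param pos current node positions
#' @return a list with `length`, `area_strain`, `lead_x`, `trail_x`,
#'   `centroid` (3-vector) and `area`, `volume`
#' @export
cell_observables <- function(mesh, rest, pos = mesh$pos) {
  g <- cpp_tri_geometry(pos, mesh$tri - 1L)
  list(length = max(pos[, 1]) - min(pos[, 1]),
       area_strain = (g$total_area - rest$S0) / rest$S0,
       lead_x = max(pos[, 1]), trail_x = min(pos[, 1]),
       centroid = colMeans(pos),
       area = g$total_area, volume = g$volume)
}

#' Buoyant mass of a spherical cell
#'
#' `m_b = (4 pi r^3 / 3)(rho - rho_f)`, the excess mass over the
#' displaced fluid measured by suspended microchannel resonators, and its
#' inverse giving the radius back from a measured buoyant mass.
#'
#' @param r cell radius (um)
#' @param rho cell density (kg/m^3)
#' @param rho_f fluid density (kg/m^3)
#' @return buoyant mass in pg
#' @examples
#' buoyant_mass(6.5) # about 50.6 pg
#' @export
buoyant_mass <- function(r, rho = 1050, rho_f = 1006) {
  4 * pi * r^3 / 3 * (rho - rho_f) * 1e-3   # kg/m^3 -> pg/um^3
}

#' @rdname buoyant_mass
#' @param m_b buoyant mass (pg)
#' @export
radius_from_buoyant_mass <- function(m_b, rho = 1050, rho_f = 1006) {
  if (rho == rho_f) stop("cell and fluid density are equal: buoyant mass is identically zero")
  (3 * m_b / (4 * pi * (rho - rho_f) * 1e-3))^(1 / 3)
}

#' Entry and transit times from edge trajectories
#'
#' The entry time runs from the leading edge crossing the taper-entrance
#' plane to the trailing edge crossing the constriction-entrance plane;
#' the transit time from that instant to the trailing edge crossing the
#' constriction-exit plane. Crossing times are linearly interpolated
#' between samples.
#'
#' @param series a data frame with columns `t_us`, `lead_x_um`,
#'   `trail_x_um` (monotone time stamps)
#' @param x_taper,x_entry,x_exit the three plane positions (um)
#' @return a list with `entry_time`, `transit_time` (us; `NA` with the
#'   corresponding flag set if a plane is never crossed), `t_taper`,
#'   `t_enter`, `t_exit`, and logical `complete`
#' @export
detect_entry_transit <- function(series, x_taper, x_entry, x_exit) {
  stopifnot(all(diff(series$t_us) > 0))
  t_taper <- crossing_time(series$t_us, series$lead_x_um, x_taper)
  t_enter <- crossing_time(series$t_us, series$trail_x_um, x_entry)
  t_exit <- crossing_time(series$t_us, series$trail_x_um, x_exit)
  list(entry_time = t_enter - t_taper,
       transit_time = t_exit - t_enter,
       t_taper = t_taper, t_enter = t_enter, t_exit = t_exit,
       complete = !is.na(t_exit))
}

# first upward crossing of `level` by the piecewise-linear trace (t, x)
crossing_time <- function(t, x, level) {
  above <- x >= level
  if (above[1]) return(t[1])
  k <- which(!above[-length(above)] & above[-1])
  if (!length(k)) return(NA_real_)
  k <- k[1]
  t[k] + (level - x[k]) * (t[k + 1] - t[k]) / (x[k + 1] - x[k])
}
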