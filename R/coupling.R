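#' Reference friction coefficient for a given fluid viscosity
#'
#' The dissipative fluid-membrane coupling coefficient was calibrated for
#' a reference sphere (radius 4 um, 393 nodes) in three fluids; this
#' interpolates/extrapolates linearly on those calibration points using
#' the two nearest tabulated viscosities.
#'
#' @param visc dynamic viscosity (mPa s)
#' @return the reference coefficient `xi_ref` (nN s/m)
#' @examples
#' xi_ref_for_viscosity(1.0)   # 1.18, a calibration point
#' xi_ref_for_viscosity(0.785) # 0.922, the cell-medium value
#' @export
xi_ref_for_viscosity <- function(visc) {
  stopifnot(visc > 0)
  tab_v <- c(1.0, 1.3, 1.5375)
  tab_xi <- c(1.18, 1.54, 1.82)
  if (visc < 0.5 || visc > 2.5)
    warning("viscosity ", visc, " mPa s is far outside the calibrated range; extrapolating")
  vapply(visc, function(v) {
    o <- order(abs(tab_v - v))[1:2]
    o <- sort(o)
    v1 <- tab_v[o[1]]; v2 <- tab_v[o[2]]
    tab_xi[o[1]] + (v - v1) * (tab_xi[o[2]] - tab_xi[o[1]]) / (v2 - v1)
  }, numeric(1))
}

#' Per-node coupling coefficient for an immersed object
#'
#' Scales the reference coefficient to an object with `n` membrane nodes
#' and surface area `S`:
#' `xi = (n_ref / n) sqrt(S / S_ref) xi_ref`
#' with `n_ref = 393` and `S_ref` the area of the 4 um reference sphere.
#'
#' @param n node count of the object's mesh
#' @param S surface area of the object (um^2)
#' @param xi_ref reference coefficient (nN s/m), e.g. from
#'   [xi_ref_for_viscosity]
#' @return the per-node coefficient `xi` (nN s/m; numerically equal in
#'   pg/us, the simulation unit)
#' @export
xi_for_object <- function(n, S, xi_ref = 0.922) {
  stopifnot(n > 0, S > 0, xi_ref > 0)
  n_ref <- 393
  S_ref <- 4 * pi * 4^2
  (n_ref / n) * sqrt(S / S_ref) * xi_ref
}

#' Interpolate the fluid velocity at arbitrary positions
#'
#' Trilinear interpolation from the 8 lattice sites surrounding each
#' point; solid sites are excluded and the remaining weights renormalised
#' (positions deep inside the solid return `NA`).
#'
#' @param lat a [fluid_lattice]
#' @param pts positions (um), n x 3
#' @param physical return um/us instead of lattice units
#' @return an n x 3 velocity matrix
#' @export
interpolate_velocity <- function(lat, pts, physical = TRUE) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  m <- lbm_moments(lat, physical = physical)
  u <- m$u
  u[is.na(u)] <- 0
  pts_lat <- pts / lat$dx - 0.5
  cpp_trilinear(u, lat$solid, lat$dims, pts_lat, lat$periodic)
}

#' Dissipative drag coupling between nodes and fluid
#'
#' The drag on node j is `F_j = xi (u - v)`, pulling the node toward the
#' local fluid velocity; the equal-and-opposite impulse `-F_j dt` is
#' spread onto the fluid with the same trilinear stencil used for
#' interpolation, so the exchange conserves momentum exactly.
#'
#' @param v node velocities (um/us), n x 3
#' @param u fluid velocities at the nodes (um/us), n x 3
#' @param xi per-node coupling coefficient (nN s/m)
#' @param sign `"dissipative"` (drag toward the fluid velocity, default)
#'   or `"literal"` for the opposite, anti-dissipative orientation kept
#'   only for comparison
#' @return a list with `force` (n x 3, nN) and `momentum_to_fluid`
#'   (n x 3, pg um/us per unit time step; deposit as `-F dt`)
#' @export
drag_and_backforce <- function(v, u, xi, sign = c("dissipative", "literal")) {
  sign <- match.arg(sign)
  s <- if (sign == "dissipative") 1 else -1
  FF <- s * xi * (u - v)
  list(force = FF, momentum_to_fluid = -FF)
}
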