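#' Cell-wall interaction parameters
#'
#' @param a repulsive scale coefficient (default 0.0001)
#' @param n_exp repulsive exponent (default 1.2)
#' @param d_cut activation threshold (um, default 0.1): both wall forces
#'   are identically zero at distances `>= d_cut`
#' @param mu_f surface friction coefficient (dimensionless; the friction
#'   magnitude is exactly `mu_f` times the repulsive magnitude)
#' @param d_min clamp distance for penetrating nodes (um)
#' @param eps_v velocity dead-band (um/us) regularising the friction
#'   direction at rest; there is no static-friction model
#' @param tangential if `TRUE`, friction opposes only the wall-tangential
#'   velocity component instead of the full nodal velocity
#' @return a `wall_params` list
#' @export
wall_params <- function(a = 1e-4, n_exp = 1.2, d_cut = 0.1, mu_f = 0,
                        d_min = 1e-3, eps_v = 1e-6, tangential = FALSE) {
  stopifnot(a >= 0, n_exp > 0, d_cut > 0, mu_f >= 0, d_min > 0, eps_v > 0)
  structure(list(a = a, n_exp = n_exp, d_cut = d_cut, mu_f = mu_f,
                 d_min = d_min, eps_v = eps_v, tangential = tangential),
            class = "wall_params")
}

#' Node-wall repulsion
#'
#' Power-law repulsion `a n / d^(n+1)` along the wall->node direction,
#' active strictly below the threshold `d_cut`. A non-positive distance is
#' a penetration event: the force is evaluated at the clamped distance
#' `d_min` and the event is counted by the callers that log it.
#'
#' @param d node-wall distance (um)
#' @param m unit vector from the wall foot point toward the node
#' @param params a [wall_params]
#' @return the force vector (nN)
#' @export
repulsive_force <- function(d, m, params = wall_params()) {
  if (d >= params$d_cut) return(c(0, 0, 0))
  de <- max(d, params$d_min)
  params$a * params$n_exp / de^(params$n_exp + 1) * m
}

#' Kinetic wall friction
#'
#' Friction of magnitude `mu_f` times the repulsion magnitude, directed
#' against the node velocity (or its wall-tangential projection). Inside
#' the velocity dead-band the force is zero.
#'
#' @param v node velocity (um/us)
#' @inheritParams repulsive_force
#' @export
friction_force <- function(v, d, m = NULL, params = wall_params()) {
  if (d >= params$d_cut || params$mu_f == 0) return(c(0, 0, 0))
  if (params$tangential && !is.null(m)) v <- v - sum(v * m) * m
  vn <- sqrt(sum(v^2))
  if (vn <= params$eps_v) return(c(0, 0, 0))
  de <- max(d, params$d_min)
  -params$mu_f * params$a * params$n_exp / de^(params$n_exp + 1) * v / vn
}

#' Distance to the nearest channel wall
#'
#' Analytic signed distance from points to the channel's wall patches: the
#' two width-profile side walls (piecewise-linear half-width, covering the
#' straight sections and the 45 degree tapers) and the two flat depth
#' walls. A tie between patches resolves to the first in the fixed order
#' upper-side, lower-side, bottom, top.
#'
#' @param pts points (um), a vector of length 3 or an n x 3 matrix
#' @param geom a [channel_geometry]
#' @return a list with `d` (signed distance, negative inside the solid)
#'   and `m` (unit wall->fluid direction per point)
#' @export
nearest_wall_distance <- function(pts, geom) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  out <- cpp_wall_distance(pts, geom$poly, geom$yc, geom$zlo, geom$zhi)
  list(d = out[, 1], m = out[, 2:4, drop = FALSE])
}
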