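#' Viscoelastic membrane parameters
#'
#' Bundles the five elastic moduli and the viscous damping coefficient of
#' the Kelvin-Voigt spring-network membrane. All values are in the
#' package's um-us-pg unit system (see [unit_map]); identification bounds
#' are handled by [ga_bounds].
#'
#' @param k_s stretching modulus of the neo-Hookean edge springs
#' @param k_b bending modulus of the dihedral hinges
#' @param k_al local-area modulus (per triangle)
#' @param k_ag global-area modulus
#' @param k_V global-volume modulus
#' @param k_visc membrane viscous damping coefficient
#' @return an `elastic_params` list
#' @export
elastic_params <- function(k_s = 0.073, k_b = 1.649, k_al = 0.969,
                           k_ag = 3.084, k_V = 0.823, k_visc = 2.481) {
  p <- list(k_s = k_s, k_b = k_b, k_al = k_al, k_ag = k_ag,
            k_V = k_V, k_visc = k_visc)
  if (any(unlist(p) < 0)) stop("elastic parameters must be non-negative")
  structure(p, class = "elastic_params")
}

#' Neo-Hookean stiffening factor
#'
#' `kappa(lambda) = (lambda^0.5 + lambda^-2.5) / (lambda + lambda^-3)`,
#' the nonlinear factor multiplying the linear edge-spring force: unity at
#' rest, softening in extension and stiffening in compression.
#'
#' @param lambda edge stretch ratio L / L0 (> 0)
#' @return the dimensionless factor
#' @examples
#' kappa_neo_hookean(1) # 1
#' @export
kappa_neo_hookean <- function(lambda) {
  if (any(lambda <= 0)) stop("stretch ratio must be positive")
  (lambda^0.5 + lambda^-2.5) / (lambda + lambda^-3)
}

force_ctx <- function(mesh, rest) {
  list(tri = mesh$tri - 1L, edges = mesh$edges - 1L,
       edge_tri = mesh$edge_tri - 1L, edge_opp = mesh$edge_opp - 1L,
       L0 = rest$L0, theta0 = rest$theta0, A0 = rest$A0,
       S0 = rest$S0, V0 = rest$V0)
}

membrane_force_component <- function(mesh, rest, pos, vel,
                                     k_s = 0, k_b = 0, k_al = 0, k_ag = 0,
                                     k_V = 0, k_visc = 0, viscous_mode = "relative") {
  cx <- force_ctx(mesh, rest)
  if (is.null(vel)) vel <- matrix(0, nrow(pos), 3)
  out <- cpp_membrane_forces(pos, vel, cx$tri, cx$edges, cx$edge_tri, cx$edge_opp,
                             cx$L0, cx$theta0, cx$A0, cx$S0, cx$V0,
                             k_s, k_b, k_al, k_ag, k_V, k_visc,
                             viscous_mode == "relative")
  if (out$n_degenerate > 0)
    stop("degenerate geometry encountered during force evaluation (",
         out$n_degenerate, " zero-area/zero-length elements)")
  out$force
}

#' Membrane force laws
#'
#' Per-node force vectors of the individual Kelvin-Voigt membrane terms:
#' neo-Hookean edge stretching, dihedral bending (restoring loads on the
#' apex vertices of each triangle pair, compensated on the shared edge so
#' every hinge is momentum-free), local-area / global-area / global-volume
#' constraints, and the membrane viscosity damper.
#'
#' @param mesh a [trimesh]
#' @param rest the [compute_rest_state] of the mesh
#' @param pos current node positions (um)
#' @param vel current node velocities (um/us); only the viscous term uses
#'   them
#' @param k_s,k_b,k_al,k_ag,k_V,k_visc the moduli (see [elastic_params])
#' @param viscous_mode `"relative"` damps the edge-relative velocity
#'   (Galilean-invariant, momentum-conserving, the default) while
#'   `"literal"` damps the absolute nodal velocity projected on each
#'   incident edge
#' @return an n-nodes x 3 matrix of forces (nN)
#' @export
stretching_forces <- function(mesh, rest, pos, k_s) {
  membrane_force_component(mesh, rest, pos, NULL, k_s = k_s)
}

#' @rdname stretching_forces
#' @export
bending_forces <- function(mesh, rest, pos, k_b) {
  membrane_force_component(mesh, rest, pos, NULL, k_b = k_b)
}

#' @rdname stretching_forces
#' @export
area_volume_forces <- function(mesh, rest, pos, k_al, k_ag, k_V) {
  membrane_force_component(mesh, rest, pos, NULL, k_al = k_al, k_ag = k_ag, k_V = k_V)
}

#' @rdname stretching_forces
#' @export
viscous_forces <- function(mesh, rest, pos, vel, k_visc,
                           viscous_mode = c("relative", "literal")) {
  viscous_mode <- match.arg(viscous_mode)
  membrane_force_component(mesh, rest, pos, vel, k_visc = k_visc,
                           viscous_mode = viscous_mode)
}

#' @rdname stretching_forces
#' @param params an [elastic_params] bundle (used by `membrane_forces`)
#' @export
membrane_forces <- function(mesh, rest, pos, vel = NULL, params = elastic_params(),
                            viscous_mode = c("relative", "literal")) {
  viscous_mode <- match.arg(viscous_mode)
  membrane_force_component(mesh, rest, pos, vel,
                           k_s = params$k_s, k_b = params$k_b, k_al = params$k_al,
                           k_ag = params$k_ag, k_V = params$k_V, k_visc = params$k_visc,
                           viscous_mode = viscous_mode)
}
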