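# shared, lazily built test objects (meshes and lattices are deterministic,
# so building each once keeps the suite fast)
.cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.cache[[key]])) .cache[[key]] <- builder()
  .cache[[key]]
}

sphere42 <- function() memo("sphere42", function() build_sphere_mesh(2, 42))
sphere162 <- function() memo("sphere162", function() build_sphere_mesh(2.5, 162))
rest162 <- function() memo("rest162", function() compute_rest_state(sphere162()))
rest42 <- function() memo("rest42", function() compute_rest_state(sphere42()))

fixture <- function() memo("fixture", function() fixture_scenario())

fixture_lat <- function(q) memo(paste0("lat", q), function() {
  sc <- fixture()
  calibrate_driving(fluid_lattice(sc$geom, dx = sc$dx, dt_lb = sc$n_sub * sc$dt), q)
})

fixture_run <- function(q, mu_f = NULL, ...) {
  sc <- fixture()
  if (is.null(mu_f)) mu_f <- sc$mu_f
  key <- paste0("run", q, "_", mu_f, "_", paste(c(...), collapse = "_"))
  memo(key, function()
    run_channel_passage(sc$mesh, q, params = sc$params,
                        wall = wall_params(mu_f = mu_f), geom = sc$geom,
                        dx = sc$dx, dt = sc$dt, n_sub = sc$n_sub,
                        max_time = 900, stall_time = 150,
                        lat = fixture_lat(q), ...))
}

# random rigid rotation matrix
random_rotation <- function() {
  qr.Q(qr(matrix(rnorm(9), 3)))
}

# independent R-side evaluation of the edge-spring force law, used as the
# oracle against the compiled kernel
stretch_oracle <- function(mesh, rest, pos, k_s) {
  F <- matrix(0, mesh$n_nodes, 3)
  for (e in seq_len(mesh$n_edges)) {
    a <- mesh$edges[e, 1]; b <- mesh$edges[e, 2]
    d <- pos[b, ] - pos[a, ]
    L <- sqrt(sum(d^2)); L0 <- rest$L0[e]
    lam <- L / L0
    kap <- (lam^0.5 + lam^-2.5) / (lam + lam^-3)
    f <- k_s * kap * (L - L0) / L0 * d / L
    F[a, ] <- F[a, ] + f
    F[b, ] <- F[b, ] - f
  }
  F
}
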