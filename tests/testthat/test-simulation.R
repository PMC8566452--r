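test_that("velocity Verlet preserves free motion and matches ballistic closed forms", {
  pos <- matrix(c(0, 0, 0), 1)
  vel <- matrix(c(0.3, -0.1, 0.2), 1)
  st <- list(pos = pos, vel = vel)
  for (i in 1:100) st <- integrate_step(st$pos, st$vel, function(p, v) 0 * p,
                                        dt = 0.05, mass = 2)
  expect_equal(st$pos, pos + 100 * 0.05 * vel, tolerance = 1e-13)
  expect_equal(st$vel, vel, tolerance = 1e-15)

  # constant force: exact quadratic trajectory for Verlet
  FF <- matrix(c(0.4, 0, -0.2), 1)
  st <- list(pos = pos, vel = 0 * vel)
  n <- 200; dt <- 0.02; m <- 1.7
  for (i in 1:n) st <- integrate_step(st$pos, st$vel, function(p, v) FF, dt, m)
  t_tot <- n * dt
  expect_equal(st$pos, 0.5 * FF / m * t_tot^2, tolerance = 1e-10)
})

test_that("a harmonic two-node spring keeps its energy over 1e5 steps", {
  k <- 1; m <- 1; L0 <- 1
  force <- function(p, v) {
    d <- p[2, ] - p[1, ]
    L <- sqrt(sum(d^2))
    f <- k * (L - L0) * d / L
    rbind(f, -f)
  }
  st <- list(pos = rbind(c(-0.6, 0, 0), c(0.6, 0, 0)), vel = matrix(0, 2, 3))
  energy <- function(s) {
    L <- sqrt(sum((s$pos[2, ] - s$pos[1, ])^2))
    0.5 * k * (L - L0)^2 + 0.5 * m * sum(s$vel^2)
  }
  e0 <- energy(st)
  dt <- 0.01   # ~ 1/140 of the oscillation period
  for (i in 1:1e5) st <- integrate_step(st$pos, st$vel, force, dt, m)
  expect_lt(abs(energy(st) / e0 - 1), 0.001)
})

test_that("channel variants have the stated cross-sections and nesting", {
  g3 <- channel_geometry("model3")
  expect_equal(g3$width * g3$depth, 90)        # 6 x 15 um^2
  expect_equal(g3$x_entry - g3$x_taper, 12)    # 45 degree taper, (30-6)/2
  g4 <- channel_geometry("model4")
  # entry part only: domain ends before a full 50 um bore
  expect_lt(g4$x_exit - g4$x_entry, 50)
  expect_equal(g4$Lx, g4$x_exit)
  g1 <- channel_geometry("model1")
  expect_gt(g1$Lx, g3$Lx)
  expect_error(channel_geometry("model3", width = 2, upstream_width = 30) |>
                 build_channel(dx = 1), "under-resolved")
})

test_that("voxelised channels are watertight", {
  for (variant in c("model3", "model4")) {
    sc_geom <- channel_geometry(variant, width = 6, depth = 8, length = 20,
                                upstream_width = 14,
                                upstream_length = 6, downstream_length = 6)
    ch <- build_channel(sc_geom, dx = 1)
    mask <- array(ch$solid, ch$dims)
    # every transverse boundary layer is solid: no leak out of the domain
    expect_true(all(mask[, 1, ] == 1L))
    expect_true(all(mask[, ch$dims[2], ] == 1L))
    expect_true(all(mask[, , 1] == 1L))
    expect_true(all(mask[, , ch$dims[3]] == 1L))
    # the constriction itself is open
    expect_gt(sum(mask == 0L), 0)
  }
  # constriction cross-section voxel count matches width x depth at dx = 1
  ch3 <- build_channel(channel_geometry("model3"), dx = 1)
  g3 <- channel_geometry("model3")
  i_mid <- which.min(abs(ch3$x - (g3$x_entry + g3$x_exit) / 2))
  mask <- array(ch3$solid, ch3$dims)
  expect_equal(sum(mask[i_mid, , ] == 0L), 90)
})

test_that("stretching a cell gives monotone diameters and linear-response scaling", {
  m <- sphere42()
  p <- elastic_params(0.05, 0.05, 0.02, 0.5, 0.5, 0.3)
  forces <- c(0, 0.02, 0.05, 0.1)
  res <- run_stretch(m, forces, params = p, contact_fraction = 0.15)
  # zero load returns the rest diameters exactly
  expect_equal(res$axial[1], max(m$pos[, 1]) - min(m$pos[, 1]), tolerance = 1e-12)
  expect_equal(res$transverse[1], max(m$pos[, 2]) - min(m$pos[, 2]), tolerance = 1e-12)
  expect_true(all(diff(res$axial) > 0))
  expect_true(all(diff(res$transverse) <= 0))

  # doubling every modulus halves the small-strain deformation within 5%
  p2 <- elastic_params(0.1, 0.1, 0.04, 1, 1, 0.3)
  r1 <- run_stretch(m, 0.02, params = p, contact_fraction = 0.15)
  r2 <- run_stretch(m, 0.02, params = p2, contact_fraction = 0.15)
  d1 <- r1$axial - res$axial[1]
  d2 <- r2$axial - res$axial[1]
  expect_lt(abs(d1 / d2 - 2), 0.05 * 2)
})

test_that("passage requires flow: zero flow rate stalls with no net displacement", {
  sc <- fixture()
  lat0 <- fluid_lattice(sc$geom, dx = sc$dx, dt_lb = sc$n_sub * sc$dt)
  res <- run_channel_passage(sc$mesh, 0, params = sc$params,
                             wall = wall_params(), geom = sc$geom,
                             dx = sc$dx, dt = sc$dt, n_sub = sc$n_sub,
                             max_time = 400, stall_time = 60, lat = lat0)
  expect_true(res$stalled)
  drift <- abs(res$series$centroid_x_um - res$series$centroid_x_um[1])
  expect_lt(max(drift), 0.05)
})

test_that("a passage rerun with the same configuration is bit-identical", {
  sc <- fixture()
  args <- list(sc$mesh, 20, params = sc$params, wall = wall_params(mu_f = 0.2),
               geom = sc$geom, dx = sc$dx, dt = sc$dt, n_sub = sc$n_sub,
               max_time = 900, stall_time = 150, lat = fixture_lat(20))
  r1 <- do.call(run_channel_passage, args)
  r2 <- do.call(run_channel_passage, args)
  expect_identical(r1$series, r2$series)
  expect_identical(r1$final_pos, r2$final_pos)
  expect_identical(r1$entry_time, r2$entry_time)
})

test_that("the cell volume stays within 2% of rest during a fixture passage", {
  r <- fixture_run(10)
  expect_lt(max(abs(r$series$volume_dev)), 0.02)
  expect_false(r$stalled)
  expect_true(r$completed)
})

test_that("entry time decreases with flow rate on the fixture", {
  expect_gt(fixture_run(10)$entry_time, fixture_run(20)$entry_time)
})
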