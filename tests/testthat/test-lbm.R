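blank_box <- function(dims, dt_lb = 0.1) {
  fluid_lattice(mask = list(solid = rep(0L, prod(dims)), dims = as.integer(dims)),
                dx = 1, dt_lb = dt_lb)
}

test_that("the D3Q19 equilibrium reproduces its defining moments", {
  e <- cellsqueeze:::cpp_d3q19_velocities()
  w <- cellsqueeze:::cpp_d3q19_weights()
  expect_equal(sum(w), 1, tolerance = 1e-15)
  # zero velocity: pure weights
  f0 <- lbm_equilibrium(1.7, c(0, 0, 0))
  expect_equal(as.numeric(f0), 1.7 * w, tolerance = 1e-14, ignore_attr = TRUE)
  set.seed(9)
  for (i in 1:5) {
    rho <- runif(1, 0.5, 2)
    u <- runif(3, -0.1, 0.1)
    fe <- lbm_equilibrium(rho, u)
    expect_equal(sum(fe), rho, tolerance = 1e-12 * rho)
    expect_equal(as.numeric(fe %*% e), rho * u, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("moments agree with a brute-force 19-term summation and are linear", {
  dims <- c(3L, 3L, 3L)
  lat <- blank_box(dims)
  set.seed(21)
  lat$f <- runif(19 * prod(dims), 0.01, 1)
  m <- lbm_moments(lat)
  e <- cellsqueeze:::cpp_d3q19_velocities()
  fmat <- matrix(lat$f, ncol = 19, byrow = TRUE)
  expect_equal(m$rho, rowSums(fmat), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(m$u, (fmat %*% e) / rowSums(fmat), tolerance = 1e-12,
               ignore_attr = TRUE)
  # linearity of the raw moments in the populations
  lat2 <- lat; lat2$f <- 2 * lat$f
  expect_equal(lbm_moments(lat2)$rho, 2 * m$rho, tolerance = 1e-12)
})

test_that("collision leaves an equilibrium lattice unchanged at tau = 1", {
  dims <- c(4L, 4L, 4L)
  lat <- blank_box(dims)
  lat$tau <- 1
  ns <- prod(dims)
  lat$f <- as.numeric(t(lbm_equilibrium(rep(1.2, ns),
                                        matrix(rep(c(0.03, -0.01, 0.02), ns),
                                               ns, 3, byrow = TRUE))))
  f0 <- lat$f
  lat <- lbm_step(lat, 5)
  expect_equal(lat$f, f0, tolerance = 1e-13)
})

test_that("mass is conserved to near machine precision in a periodic box", {
  dims <- c(8L, 6L, 5L)
  lat <- blank_box(dims)
  set.seed(2)
  ns <- prod(dims)
  lat$f <- as.numeric(t(lbm_equilibrium(rep(1, ns),
                                        matrix(runif(3 * ns, -0.05, 0.05), ns, 3))))
  m0 <- sum(lat$f)
  lat <- lbm_step(lat, 1000)
  expect_lt(abs(sum(lat$f) / m0 - 1), 1e-12)
})

test_that("the relaxation-time map reproduces the lattice viscosity relation", {
  # tau = 1 corresponds to nu_lattice = 1/6
  nu_lat <- (1 - 0.5) / 3
  expect_equal(nu_lat, 1 / 6, tolerance = 1e-15)
  # invert: find viscosity giving tau = 1 at dx = 1, dt = 0.1 and check
  visc <- nu_lat * 1^2 / 0.1 * 1006 * 1e-3
  expect_equal(lattice_tau(visc, 1006, 1, 0.1), 1, tolerance = 1e-12)
  # the production fluid is stable
  expect_gt(lattice_tau(0.785, 1006, 1, 0.01), 0.5)
})

test_that("unit conversions round-trip exactly", {
  um <- unit_map(1, 0.01, 1006)
  for (x in c(1e-3, 0.7, 42)) {
    expect_equal(um$vel_from_lat(um$vel_to_lat(x)), x, tolerance = 1e-12)
    expect_equal(um$flow_from_lat(um$flow_to_lat(x)), x, tolerance = 1e-12)
    expect_equal(um$len_from_lat(um$len_to_lat(x)), x, tolerance = 1e-12)
  }
  expect_equal(convert_flow_rate(convert_flow_rate(22.8, "uL/h"), "um3/us"),
               22.8, tolerance = 1e-12)
})

test_that("a body-forced plane channel converges to the parabolic profile", {
  # plates 20 um apart; periodic axially and spanwise
  dims <- c(4L, 4L, 22L)
  solid <- array(0L, dims)
  solid[, , c(1, 22)] <- 1L
  lat <- fluid_lattice(mask = list(solid = as.integer(solid), dims = dims),
                       dx = 1, dt_lb = 0.1)
  g <- 1e-5
  lat$g <- c(g, 0, 0)
  lat <- lbm_step(lat, 8000)
  ux <- matrix(lbm_moments(lat)$u[, 1], prod(dims[1:2]))
  prof <- colMeans(ux[, 2:21])
  z <- (1:20) - 0.5
  nu <- (lat$tau - 0.5) / 3
  ana <- g / (2 * nu) * z * (20 - z)
  expect_lt(max(abs(prof - ana)) / max(ana), 0.02)
})

test_that("the Poiseuille error decreases with refinement at order >= 1.5", {
  err_at <- function(nz) {
    dims <- c(3L, 3L, nz + 2L)
    solid <- array(0L, dims)
    solid[, , c(1, nz + 2L)] <- 1L
    lat <- fluid_lattice(mask = list(solid = as.integer(solid), dims = dims),
                         dx = 20 / nz, dt_lb = 0.1 * (20 / nz)^2)
    g <- 1e-5
    lat$g <- c(g, 0, 0)
    lat <- lbm_step(lat, 6000)
    ux <- matrix(lbm_moments(lat)$u[, 1], prod(dims[1:2]))
    prof <- colMeans(ux[, 2:(nz + 1)])
    z <- ((1:nz) - 0.5)
    nu <- (lat$tau - 0.5) / 3
    ana <- g / (2 * nu) * z * (nz - z)
    sqrt(mean((prof - ana)^2)) / max(ana)
  }
  e10 <- err_at(10)
  e20 <- err_at(20)
  order <- log2(e10 / e20)
  expect_gt(order, 1.5)
})

test_that("driving calibration is linear in the target and zero at zero", {
  sc <- fixture()
  lat0 <- fluid_lattice(sc$geom, dx = 1, dt_lb = 0.2)
  expect_identical(calibrate_driving(lat0, 0)$g, c(0, 0, 0))
  # deep Stokes regime (Re << 1): doubling the target doubles the force
  s1 <- calibrate_driving(fluid_lattice(sc$geom, dx = 1, dt_lb = 0.2), 0.5,
                          tol = 0.002)
  s2 <- calibrate_driving(fluid_lattice(sc$geom, dx = 1, dt_lb = 0.2), 1,
                          tol = 0.002)
  expect_lt(abs(s2$g[1] / s1$g[1] - 2), 0.02 * 2)
  lat1 <- fixture_lat(10)
  lat2 <- fixture_lat(20)
  # achieved flow rates are within the 1% calibration contract
  expect_lt(abs(attr(lat1, "flow_rate") / 10 - 1), 0.01)
  expect_lt(abs(attr(lat2, "flow_rate") / 20 - 1), 0.01)
})

test_that("negative populations raise an instability error", {
  dims <- c(4L, 4L, 4L)
  lat <- blank_box(dims, dt_lb = 0.1)
  lat$g <- c(0.8, 0, 0)  # absurd driving
  expect_error(lbm_step(lat, 200), "negative population|unstable")
})
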