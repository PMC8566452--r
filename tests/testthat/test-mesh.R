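test_that("icosahedron subdivision level 0 has the exact classic counts", {
  m <- build_sphere_mesh(1, 12)
  expect_identical(m$n_nodes, 12L)
  expect_identical(m$n_tri, 20L)
  expect_identical(m$n_edges, 30L)
  expect_identical(m$n_nodes - m$n_edges + m$n_tri, 2L)
})

test_that("sphere meshes hit the requested node count and closed-form geometry", {
  m <- build_sphere_mesh(6.5, 393)
  expect_identical(m$n_nodes, 393L)             # within 15% required; exact achieved
  expect_identical(m$n_nodes - m$n_edges + m$n_tri, 2L)
  g <- mesh_geometry(m)
  expect_lt(abs(g$area / (4 * pi * 6.5^2) - 1), 0.03)
  expect_lt(abs(g$volume / (4 * pi * 6.5^3 / 3) - 1), 0.03)
  # writable and re-loadable through the plain-text format
  path <- withr::local_tempfile(fileext = ".txt")
  write_mesh(m, path)
  m2 <- read_mesh(path)
  expect_identical(m2$n_nodes, 393L)
  expect_equal(m2$pos, m$pos, tolerance = 1e-12, ignore_attr = TRUE)

  m4 <- build_sphere_mesh(4, 362)
  expect_lt(abs(mesh_geometry(m4)$area / (4 * pi * 16) - 1), 0.03)
  expect_lt(abs(m4$n_nodes / 362 - 1), 0.15)
})

test_that("node counts below an icosahedron are rejected", {
  expect_error(build_sphere_mesh(1, 11), "at least 12")
  expect_error(build_sphere_mesh(-1, 42), "positive")
})

test_that("rest state of the regular tetrahedron matches closed forms", {
  # vertices of an edge-length 2*sqrt(2) regular tetrahedron
  tet <- trimesh(rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)),
                 rbind(c(1, 2, 3), c(1, 4, 2), c(1, 3, 4), c(2, 4, 3)))
  rs <- compute_rest_state(tet)
  edge <- 2 * sqrt(2)
  expect_equal(rs$S0, sqrt(3) * edge^2, tolerance = 1e-12)
  expect_equal(rs$V0, sqrt(2) / 12 * edge^3, tolerance = 1e-12)
  expect_equal(rs$L0, rep(edge, 6), tolerance = 1e-12, ignore_attr = TRUE)
  # rigid translation leaves every rest quantity unchanged
  rs2 <- compute_rest_state(tet, sweep(tet$pos, 2, c(3, -7, 11), "+"))
  expect_equal(rs2, rs, tolerance = 1e-12)
})

test_that("geometry queries respect identity, scaling and rotation", {
  m <- sphere42()
  rest <- rest42()
  g <- mesh_geometry(m, rest = rest)
  expect_equal(g$stretch, rep(1, m$n_edges), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(g$dihedral, rest$theta0, tolerance = 1e-12, ignore_attr = TRUE)

  g2 <- mesh_geometry(m, 2 * m$pos, rest = rest)
  expect_equal(g2$stretch, rep(2, m$n_edges), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(g2$area, 4 * g$area, tolerance = 1e-12)
  expect_equal(g2$volume, 8 * g$volume, tolerance = 1e-12)

  set.seed(42)
  for (i in 1:3) {
    R <- random_rotation()
    gr <- mesh_geometry(m, m$pos %*% t(R), rest = rest)
    expect_equal(gr$stretch, g$stretch, tolerance = 1e-10)
    expect_equal(gr$dihedral, g$dihedral, tolerance = 1e-10)
    expect_equal(gr$area, g$area, tolerance = 1e-10)
    expect_equal(abs(gr$volume), abs(g$volume), tolerance = 1e-10)
  }
})

test_that("closed meshes satisfy the divergence identity sum(area * normal) = 0", {
  for (m in list(sphere42(), sphere162())) {
    g <- mesh_geometry(m)
    s <- colSums(g$tri_area * g$tri_normal)
    expect_lt(max(abs(s)), 1e-9 * g$area)
  }
})

test_that("two unit triangles folded at a right angle give dihedral pi/2", {
  # shared edge A-B along z; apexes fold so the interior angle is 90 deg
  pos <- rbind(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0.5), c(0, 1, 0.5))
  tri <- rbind(c(0L, 2L, 1L), c(0L, 1L, 3L))   # consistent orientation
  th <- cellsqueeze:::cpp_dihedrals(pos, tri,
                                    matrix(c(0L, 1L), 1), matrix(c(0L, 1L), 1),
                                    matrix(c(2L, 3L), 1))
  expect_equal(th, pi / 2, tolerance = 1e-12)
})

test_that("non-manifold and inverted meshes are rejected with diagnostics", {
  # an open bowl: one face of the tetrahedron removed
  expect_error(trimesh(rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)),
                       rbind(c(1, 2, 3), c(1, 4, 2), c(1, 3, 4))),
               "non-manifold|exactly 2")
  # inward orientation is repaired, not rejected: volume comes out positive
  tet <- trimesh(rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)),
                 rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4)))
  expect_gt(mesh_geometry(tet)$volume, 0)
})

test_that("the biconcave RBC mesh is a closed manifold with the classic shape", {
  m <- biconcave_rbc_mesh(3.91, 374)
  expect_identical(m$n_nodes, 374L)
  expect_identical(m$n_nodes - m$n_edges + m$n_tri, 2L)
  g <- mesh_geometry(m)
  expect_gt(g$volume, 0)
  # dimple: the axis is thinner than the rim
  r_xy <- sqrt(m$pos[, 1]^2 + m$pos[, 2]^2)
  axis_th <- max(abs(m$pos[r_xy < 1, 3]))
  rim_th <- max(abs(m$pos[r_xy > 2.5 & r_xy < 3.5, 3]))
  expect_lt(axis_th, rim_th)
  expect_lt(abs(max(r_xy) / 3.91 - 1), 0.05)
})
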