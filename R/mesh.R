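#' Triangulated closed surface mesh
#'
#' Constructs a `trimesh` from node positions and outward-oriented
#' triangles, builds the edge adjacency used by the membrane force laws,
#' and validates that the surface is a closed orientable 2-manifold.
#'
#' @param pos numeric matrix, one row per node (um)
#' @param tri integer matrix, one row per triangle, 1-based vertex indices
#'   ordered so normals point outward; if the signed enclosed volume is
#'   negative the orientation of every triangle is flipped
#' @return a `trimesh`: list with `pos`, `tri`, `edges` (each row a vertex
#'   pair, `edge_tri` the two adjacent triangles, `edge_opp` the opposite
#'   vertex in each), plus node/edge/triangle counts
#' @details Fails if any edge is not shared by exactly two triangles, if
#'   the two adjacent triangles traverse the edge in the same direction
#'   (inconsistent orientation), or if the Euler characteristic
#'   V - E + F differs from 2.
#' @export
trimesh <- function(pos, tri) {
  pos <- as.matrix(pos)
  storage.mode(pos) <- "double"
  tri <- as.matrix(tri)
  storage.mode(tri) <- "integer"
  if (ncol(pos) != 3L) stop("node positions must have 3 columns")
  if (ncol(tri) != 3L) stop("triangles must have 3 columns")
  if (any(tri < 1L) || any(tri > nrow(pos))) stop("triangle vertex index out of range")

  # orient outward (positive signed volume)
  vol <- cpp_tri_geometry(pos, tri - 1L)$volume
  if (vol < 0) {
    tri <- tri[, c(1L, 3L, 2L), drop = FALSE]
    vol <- -vol
  }
  if (vol == 0) stop("mesh encloses zero signed volume")

  # directed edges of all triangles; an undirected edge must appear exactly
  # twice, once per direction
  M <- nrow(tri)
  from <- c(tri[, 1], tri[, 2], tri[, 3])
  to <- c(tri[, 2], tri[, 3], tri[, 1])
  opp <- c(tri[, 3], tri[, 1], tri[, 2])
  tid <- rep.int(seq_len(M), 3L)
  a <- pmin(from, to)
  b <- pmax(from, to)
  key <- paste(a, b)
  cnt <- table(key)
  bad <- names(cnt)[cnt != 2L]
  if (length(bad)) {
    stop("non-manifold mesh: edge(s) ", paste(utils::head(bad, 3), collapse = ", "),
         " not shared by exactly 2 triangles")
  }
  ord <- order(a, b, from)            # within a key: the (a -> b) copy first
  a <- a[ord]; b <- b[ord]; from <- from[ord]
  opp <- opp[ord]; tid <- tid[ord]
  i1 <- seq(1L, length(a), by = 2L)
  i2 <- i1 + 1L
  if (any(from[i1] == from[i2])) {
    stop("inconsistent triangle orientation at edge ",
         paste(a[i1][from[i1] == from[i2]][1], b[i1][from[i1] == from[i2]][1]))
  }
  edges <- cbind(a[i1], b[i1])
  edge_tri <- cbind(tid[i1], tid[i2])
  edge_opp <- cbind(opp[i1], opp[i2])

  V <- nrow(pos); E <- nrow(edges)
  if (V - E + M != 2L) {
    stop("mesh is not a closed sphere-topology surface (V - E + F = ",
         V - E + M, ", expected 2)")
  }
  structure(list(pos = pos, tri = tri, edges = edges, edge_tri = edge_tri,
                 edge_opp = edge_opp, n_nodes = V, n_edges = E, n_tri = M),
            class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  g <- cpp_tri_geometry(x$pos, x$tri - 1L)
  cat("trimesh:", x$n_nodes, "nodes,", x$n_edges, "edges,", x$n_tri, "triangles\n")
  cat(sprintf("  surface area %.4g um^2, enclosed volume %.4g um^3\n",
              g$total_area, g$volume))
  invisible(x)
}

icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(pos = v, tri = f)
}

subdivide_sphere <- function(pos, tri) {
  # midpoint subdivision with projection back to the unit sphere
  M <- nrow(tri)
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  mid_env <- new.env(hash = TRUE)
  newpos <- list()
  nextid <- nrow(pos)
  midpoint <- function(i, j) {
    k <- key(i, j)
    id <- mid_env[[k]]
    if (!is.null(id)) return(id)
    p <- pos[i, ] + pos[j, ]
    p <- p / sqrt(sum(p^2))
    nextid <<- nextid + 1L
    newpos[[length(newpos) + 1L]] <<- p
    mid_env[[k]] <- nextid
    nextid
  }
  out <- matrix(0L, 4L * M, 3L)
  for (t in seq_len(M)) {
    i <- tri[t, 1]; j <- tri[t, 2]; k <- tri[t, 3]
    ij <- midpoint(i, j); jk <- midpoint(j, k); ki <- midpoint(k, i)
    out[4 * t - 3, ] <- c(i, ij, ki)
    out[4 * t - 2, ] <- c(j, jk, ij)
    out[4 * t - 1, ] <- c(k, ki, jk)
    out[4 * t, ] <- c(ij, jk, ki)
  }
  list(pos = rbind(pos, do.call(rbind, newpos)), tri = out)
}

# Collapse the shortest collapsible edge until the node count reaches
# `target`.  The link condition (the neighbourhoods of the two endpoints
# share exactly the two edge-opposite vertices) keeps the mesh manifold.
decimate_to <- function(pos, tri, target) {
  while (nrow(pos) > target) {
    ed <- unique_edges(tri)
    len <- sqrt(rowSums((pos[ed[, 1], , drop = FALSE] - pos[ed[, 2], , drop = FALSE])^2))
    adj <- vertex_adjacency(tri, nrow(pos))
    done <- FALSE
    for (e in order(len)) {
      i <- ed[e, 1]; j <- ed[e, 2]
      common <- intersect(adj[[i]], adj[[j]])
      if (length(common) != 2L) next
      mid <- pos[i, ] + pos[j, ]
      mid <- mid / sqrt(sum(mid^2))
      pos[i, ] <- mid
      tri[tri == j] <- i
      degen <- apply(tri, 1L, function(r) anyDuplicated(r) > 0L)
      tri <- tri[!degen, , drop = FALSE]
      keep <- seq_len(nrow(pos)) != j
      remap <- cumsum(keep)
      pos <- pos[keep, , drop = FALSE]
      tri[] <- remap[tri]
      done <- TRUE
      break
    }
    if (!done) stop("edge-collapse decimation stuck before reaching target node count")
  }
  list(pos = pos, tri = tri)
}

unique_edges <- function(tri) {
  a <- c(tri[, 1], tri[, 2], tri[, 3])
  b <- c(tri[, 2], tri[, 3], tri[, 1])
  e <- cbind(pmin(a, b), pmax(a, b))
  e[!duplicated(e), , drop = FALSE]
}

vertex_adjacency <- function(tri, n) {
  adj <- vector("list", n)
  e <- unique_edges(tri)
  for (r in seq_len(nrow(e))) {
    adj[[e[r, 1]]] <- c(adj[[e[r, 1]]], e[r, 2])
    adj[[e[r, 2]]] <- c(adj[[e[r, 2]]], e[r, 1])
  }
  adj
}

# tangential Laplacian smoothing with reprojection onto the unit sphere
relax_on_sphere <- function(pos, tri, iters = 30, lambda = 0.5) {
  adj <- vertex_adjacency(tri, nrow(pos))
  for (it in seq_len(iters)) {
    avg <- t(vapply(adj, function(nb) colMeans(pos[nb, , drop = FALSE]), numeric(3)))
    pos <- pos + lambda * (avg - pos)
    pos <- pos / sqrt(rowSums(pos^2))
  }
  pos
}

#' Quasi-uniform triangulated sphere mesh
#'
#' Builds a closed triangulation of a sphere with approximately
#' `target_nodes` nodes by midpoint-subdividing an icosahedron to the first
#' level at or above the target and then collapsing the shortest edges
#' (with a manifold-preserving link condition) down to the exact count,
#' followed by tangential relaxation on the sphere. Counts reachable by
#' pure subdivision (12, 42, 162, 642, ...) need no collapsing.
#'
#' @param radius sphere radius (um)
#' @param target_nodes requested node count (>= 12)
#' @return a [trimesh] centred at the origin
#' @examples
#' m <- build_sphere_mesh(6.5, 393)
#' m$n_nodes # exactly 393
#' @export
build_sphere_mesh <- function(radius, target_nodes) {
  if (radius <= 0) stop("radius must be positive")
  if (target_nodes < 12) stop("target_node_count must be at least 12")
  ic <- icosahedron()
  while (nrow(ic$pos) < target_nodes) ic <- subdivide_sphere(ic$pos, ic$tri)
  if (nrow(ic$pos) > target_nodes) {
    ic <- decimate_to(ic$pos, ic$tri, target_nodes)
    ic$pos <- relax_on_sphere(ic$pos, ic$tri, iters = 40)
  } else {
    ic$pos <- relax_on_sphere(ic$pos, ic$tri, iters = 10)
  }
  trimesh(radius * ic$pos, ic$tri)
}

#' Biconcave red-blood-cell mesh
#'
#' Maps a quasi-uniform sphere triangulation onto the standard biconcave
#' discoid parameterisation
#' `z = +/- (R0/2) sqrt(1 - w^2) (C0 + C1 w^2 + C2 w^4)` with
#' `w = r_xy / R0`, the classical fit to the human erythrocyte profile.
#' The triangulation topology is inherited from the sphere, so the surface
#' stays a closed manifold.
#'
#' @param radius disc radius R0 (um); 3.91 um gives the canonical 7.82 um
#'   diameter cell
#' @param target_nodes node count of the triangulation
#' @param coef the three profile coefficients (C0, C1, C2)
#' @return a [trimesh]
#' @export
biconcave_rbc_mesh <- function(radius = 3.91, target_nodes = 374,
                               coef = c(0.207, 2.003, -1.123)) {
  m <- build_sphere_mesh(1, target_nodes)
  p <- m$pos
  w <- sqrt(pmin(p[, 1]^2 + p[, 2]^2, 1))
  zsgn <- ifelse(p[, 3] >= 0, 1, -1)
  z <- zsgn * 0.5 * sqrt(pmax(1 - w^2, 0)) * (coef[1] + coef[2] * w^2 + coef[3] * w^4)
  trimesh(radius * cbind(p[, 1], p[, 2], z), m$tri)
}

#' Rest-state geometry of a mesh
#'
#' Computes the relaxed quantities entering the membrane force laws: rest
#' edge lengths, rest dihedral angles between adjacent triangles, rest
#' triangle areas, the rest global area and the rest enclosed volume.
#'
#' @param mesh a [trimesh]
#' @param pos optional positions overriding `mesh$pos`
#' @return a `rest_state` list with `L0`, `theta0`, `A0`, `S0`, `V0`
#' @export
compute_rest_state <- function(mesh, pos = mesh$pos) {
  stopifnot(inherits(mesh, "trimesh"))
  g <- cpp_tri_geometry(pos, mesh$tri - 1L)
  if (g$n_degenerate > 0) stop("degenerate (zero-area) triangle in rest shape")
  if (g$volume <= 0) stop("rest shape has non-positive volume")
  L0 <- cpp_edge_lengths(pos, mesh$edges - 1L)
  if (any(L0 <= 0)) stop("degenerate edge (zero rest length) at edge ", which(L0 <= 0)[1])
  theta0 <- cpp_dihedrals(pos, mesh$tri - 1L, mesh$edges - 1L,
                          mesh$edge_tri - 1L, mesh$edge_opp - 1L)
  if (anyNA(theta0) || any(theta0 <= 0) || any(theta0 >= 2 * pi))
    stop("invalid rest dihedral at edge ", which(is.na(theta0) | theta0 <= 0)[1])
  structure(list(L0 = L0, theta0 = theta0, A0 = g$area,
                 S0 = g$total_area, V0 = g$volume),
            class = "rest_state")
}

#' Geometric queries on a deformed configuration
#'
#' Evaluates, for node positions `pos` on the topology of `mesh`, the
#' per-edge stretch ratios and dihedral angles, per-triangle areas,
#' centroids, unit outward normals and vertex-to-centroid distance sums,
#' and the global surface area and signed enclosed volume.
#'
#' @param mesh a [trimesh]
#' @param pos node positions (defaults to the mesh's own)
#' @param rest optional [compute_rest_state] result; needed for stretches
#' @return a list with `stretch`, `edge_length`, `dihedral`, `tri_area`,
#'   `tri_normal`, `tri_centroid`, `t2sum`, `area`, `volume` and a logical
#'   `degenerate` flag per triangle
#' @export
mesh_geometry <- function(mesh, pos = mesh$pos, rest = NULL) {
  stopifnot(inherits(mesh, "trimesh"), nrow(pos) == mesh$n_nodes)
  g <- cpp_tri_geometry(pos, mesh$tri - 1L)
  len <- cpp_edge_lengths(pos, mesh$edges - 1L)
  th <- cpp_dihedrals(pos, mesh$tri - 1L, mesh$edges - 1L,
                      mesh$edge_tri - 1L, mesh$edge_opp - 1L)
  list(stretch = if (!is.null(rest)) len / rest$L0,
       edge_length = len, dihedral = th,
       tri_area = g$area, tri_normal = g$normal, tri_centroid = g$centroid,
       t2sum = g$t2sum, area = g$total_area, volume = g$volume,
       degenerate = g$area <= 1e-12 * mean(g$area))
}

#' Read and write the plain-text mesh format
#'
#' The format is a header line `nodes N triangles M`, then N lines of
#' `x y z` coordinates (um), then M lines of `i j k` 0-based vertex
#' indices.
#'
#' @param path file path
#' @return `read_mesh` returns a [trimesh]
#' @export
read_mesh <- function(path) {
  hdr <- scan(path, what = character(), nmax = 4, quiet = TRUE)
  if (length(hdr) != 4 || hdr[1] != "nodes" || hdr[3] != "triangles")
    stop("malformed mesh header in ", path)
  n <- as.integer(hdr[2]); m <- as.integer(hdr[4])
  dat <- scan(path, what = numeric(), skip = 1, quiet = TRUE)
  if (length(dat) != 3 * n + 3 * m) stop("mesh file length mismatch in ", path)
  pos <- matrix(dat[seq_len(3 * n)], ncol = 3, byrow = TRUE)
  tri <- matrix(as.integer(dat[3 * n + seq_len(3 * m)]), ncol = 3, byrow = TRUE) + 1L
  trimesh(pos, tri)
}

#' @rdname read_mesh
#' @param mesh a [trimesh] to write
#' @export
write_mesh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("nodes %d triangles %d", mesh$n_nodes, mesh$n_tri), con)
  utils::write.table(format(mesh$pos, digits = 17, scientific = TRUE, trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(mesh$tri - 1L, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
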