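#' Write a cell surface as legacy VTK PolyData
#'
#' ASCII legacy VTK with the node coordinates as POINTS, the triangles
#' as POLYGONS, and optionally a per-node velocity as point data, the
#' format consumed directly by ParaView.
#'
#' @param mesh a [trimesh]
#' @param path output file
#' @param pos node positions overriding `mesh$pos`
#' @param velocity optional n x 3 per-node velocity for the point data
#' @export
write_vtk_cell <- function(mesh, path, pos = mesh$pos, velocity = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(pos); m <- mesh$n_tri
  writeLines(c("# vtk DataFile Version 2.0", "cell surface", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d float", n)), con)
  utils::write.table(format(pos, digits = 9, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("POLYGONS %d %d", m, 4 * m), con)
  utils::write.table(cbind(3L, mesh$tri - 1L), con,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(velocity)) {
    writeLines(c(sprintf("POINT_DATA %d", n), "VECTORS velocity float"), con)
    utils::write.table(format(velocity, digits = 9, trim = TRUE), con,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Write the fluid as legacy VTK StructuredPoints
#'
#' The density and velocity fields of a [fluid_lattice] on its regular
#' grid, with solid sites zero-filled.
#'
#' @param lat a [fluid_lattice]
#' @param path output file
#' @export
write_vtk_fluid <- function(lat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  d <- lat$dims
  m <- lbm_moments(lat, physical = TRUE)
  u <- m$u; u[is.na(u)] <- 0
  rho <- m$rho; rho[is.na(rho)] <- 0
  writeLines(c("# vtk DataFile Version 2.0", "fluid fields", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               sprintf("ORIGIN %g %g %g", lat$dx / 2, -lat$dx / 2, -lat$dx / 2),
               sprintf("SPACING %g %g %g", lat$dx, lat$dx, lat$dx),
               sprintf("POINT_DATA %d", prod(d)),
               "VECTORS velocity float"), con)
  utils::write.table(format(u, digits = 9, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(c("SCALARS density float 1", "LOOKUP_TABLE default"), con)
  writeLines(format(rho, digits = 9, trim = TRUE), con)
  invisible(path)
}

# minimal legacy-VTK PolyData reader used by the round-trip tests
read_vtk_points <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)[1]
  n <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  vals <- scan(text = paste(lines[(ip + 1):length(lines)], collapse = " "),
               what = numeric(), n = 3 * n, quiet = TRUE)
  matrix(vals, ncol = 3, byrow = TRUE)
}

#' Write the passage metric time series as CSV
#'
#' Columns `t_us`, `length_um`, `area_strain`, `lead_x_um`,
#' `trail_x_um`, `centroid_x_um`, `mean_speed_um_per_us`.
#'
#' @param result a `passage_result` from [run_channel_passage]
#' @param path output file
#' @export
write_metrics_csv <- function(result, path) {
  utils::write.csv(result$series[, c("t_us", "length_um", "area_strain",
                                     "lead_x_um", "trail_x_um",
                                     "centroid_x_um", "mean_speed_um_per_us")],
                   path, row.names = FALSE)
  invisible(path)
}
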