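#' Desk-scale fixture scenario
#'
#' A reduced-resolution but physically complete passage setup used for
#' testing and closed-loop identification: a 162-node cell of radius
#' 2.5 um squeezing through a 3 x 6 um^2 constriction (the same 45 degree
#' tapered geometry as the production channel, scaled down so a full
#' passage integrates in seconds), with every force term of the model
#' active. The generating parameter set plays the role of the unknown
#' "true" cell in recovery tests.
#'
#' @param node_count mesh nodes of the fixture cell
#' @param cell_radius cell radius (um); must exceed the constriction
#'   half-width so the cell has to deform
#' @param width,depth,length constriction dimensions (um)
#' @param upstream_width wide-section width (um)
#' @param flow_rates the two fixture flow rates (uL/h)
#' @param params generating [elastic_params]
#' @param mu_f generating surface friction coefficient
#' @param dx,dt,n_sub numerics (see [run_channel_passage])
#' @param seed scenario seed (recorded; the passage solver itself is
#'   deterministic)
#' @return a `fixture_scenario` list with the mesh, geometry and all
#'   settings
#' @export
fixture_scenario <- function(node_count = 162, cell_radius = 3,
                             width = 3, depth = 7, length = 10,
                             upstream_width = 10,
                             flow_rates = c(10, 20),
                             params = elastic_params(k_s = 0.5, k_b = 0.8,
                                                     k_al = 0.05, k_ag = 0.9,
                                                     k_V = 3, k_visc = 1.5),
                             mu_f = 0.45, dx = 1, dt = 0.02, n_sub = 10,
                             seed = 1) {
  geom <- channel_geometry("model3", width = width, depth = depth,
                           length = length, upstream_width = upstream_width,
                           upstream_length = 2 * cell_radius + 2,
                           downstream_length = 4)
  mesh <- build_sphere_mesh(cell_radius, node_count)
  structure(list(mesh = mesh, geom = geom, flow_rates = flow_rates,
                 params = params, mu_f = mu_f, dx = dx, dt = dt,
                 n_sub = n_sub, seed = seed),
            class = "fixture_scenario")
}

#' Passage simulator bound to a fixture scenario
#'
#' Wraps [run_channel_passage] on the scenario's mesh and channel into
#' the `(params, mu_f, flow_rate, stage)` interface consumed by
#' [identify_cell]. Calibrated steady lattices are cached per flow rate,
#' and `stage = "entry"` stops the integration once the cell has fully
#' entered the constriction.
#'
#' @param scenario a [fixture_scenario]
#' @param max_time simulated-time budget per run (us); runs that do not
#'   finish in budget report `NA` times (scored `+Inf` by the GA, like
#'   crashed simulations)
#' @export
passage_simulator <- function(scenario, max_time = 900) {
  lat_cache <- new.env(parent = emptyenv())
  geom <- scenario$geom
  function(params, mu_f, flow_rate, stage = "full") {
    key <- paste0("q", flow_rate)
    lat <- lat_cache[[key]]
    if (is.null(lat)) {
      lat <- fluid_lattice(geom, dx = scenario$dx,
                           dt_lb = scenario$n_sub * scenario$dt)
      if (flow_rate > 0) lat <- calibrate_driving(lat, flow_rate)
      lat_cache[[key]] <- lat
    }
    if (!inherits(params, "elastic_params")) params <- do.call(elastic_params, as.list(params))
    entry_only <- identical(stage, "entry")
    res <- run_channel_passage(scenario$mesh, flow_rate, params = params,
                               wall = wall_params(mu_f = mu_f),
                               geom = geom, dx = scenario$dx, dt = scenario$dt,
                               n_sub = scenario$n_sub,
                               max_time = if (entry_only) 0.7 * max_time else max_time,
                               stall_time = 150, lat = lat,
                               stop_after = if (entry_only) "entry" else "exit")
    list(entry_time = res$entry_time, transit_time = res$transit_time,
         stalled = res$stalled)
  }
}

#' Synthetic passage-time table
#'
#' Runs the fixture simulator with the scenario's generating parameters
#' at each flow rate and tabulates the resulting entry and transit times,
#' emulating an experimental passage-time table. The generating
#' parameters are attached as the `"ground_truth"` attribute for recovery
#' tests; stalled flow rates are dropped with a warning.
#'
#' @param scenario a [fixture_scenario]
#' @param flow_rates flow rates (uL/h); defaults to the scenario's
#' @return a tibble with `flow_rate`, `entry_time`, `transit_time`
#' @export
make_passage_table <- function(scenario, flow_rates = scenario$flow_rates) {
  sim <- passage_simulator(scenario)
  rows <- lapply(flow_rates, function(fr) {
    r <- sim(scenario$params, scenario$mu_f, fr, stage = "full")
    if (isTRUE(r$stalled) || !is.finite(r$transit_time)) {
      warning("fixture cell stalled at ", fr, " uL/h; flow rate excluded")
      return(NULL)
    }
    tibble::tibble(flow_rate = fr, entry_time = r$entry_time,
                   transit_time = r$transit_time)
  })
  out <- do.call(rbind, rows)
  attr(out, "ground_truth") <- c(unlist(scenario$params), mu_f = scenario$mu_f)
  out
}

#' Synthetic stretch reference table
#'
#' Quasi-static force-diameter curve of a cell under axial stretching,
#' standing in for an optical-tweezers reference dataset in closed-loop
#' tests of the stretch-based identification.
#'
#' @param mesh the cell [trimesh]
#' @param params generating [elastic_params]
#' @param forces applied loads (nN)
#' @param ... passed to [run_stretch]
#' @return a tibble with `force`, `axial`, `transverse`; ground truth in
#'   the `"ground_truth"` attribute
#' @export
make_stretch_table <- function(mesh, params, forces, ...) {
  out <- run_stretch(mesh, forces, params = params, ...)
  keep <- attr(out, "converged")
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " non-converged force point(s)")
    out <- out[keep, ]
  }
  attr(out, "ground_truth") <- unlist(params)
  out
}

#' Write all fixture artifacts to a directory
#'
#' Emits the fixture mesh (plain-text format), the synthetic
#' passage-time table (`exp.csv`), the generating parameters
#' (`params.json`) and the channel/numerics configuration (`run.cfg`).
#'
#' @param dir output directory (created if missing)
#' @param scenario a [fixture_scenario]
#' @return the directory, invisibly
#' @export
write_fixtures <- function(dir, scenario = fixture_scenario()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mesh(scenario$mesh, file.path(dir, "cell_mesh.txt"))
  tab <- make_passage_table(scenario)
  utils::write.csv(tab, file.path(dir, "exp.csv"), row.names = FALSE)
  jsonlite::write_json(c(as.list(scenario$params), list(mu_f = scenario$mu_f)),
                       file.path(dir, "params.json"), auto_unbox = TRUE, digits = NA)
  g <- scenario$geom
  writeLines(c(sprintf("variant = %s", g$variant),
               sprintf("constriction_width_um = %g", g$width),
               sprintf("depth_um = %g", g$depth),
               sprintf("constriction_length_um = %g", g$length),
               sprintf("upstream_width_um = %g", g$upstream_width),
               sprintf("dx_um = %g", scenario$dx),
               sprintf("dt_us = %g", scenario$dt),
               sprintf("n_sub = %d", scenario$n_sub),
               sprintf("seed = %d", scenario$seed)),
             file.path(dir, "run.cfg"))
  invisible(dir)
}
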