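#' Run configuration
#'
#' All numerical and physical defaults of a passage simulation in one
#' place: time step 0.01 us, lattice resolution 1 um, medium viscosity
#' 0.785 mPa s and density 1006 kg/m^3, cell density 1050 kg/m^3,
#' reference coupling coefficient 0.922 nN s/m, repulsion scale 0.0001,
#' exponent 1.2 and activation threshold 0.1 um.
#'
#' @param ... overrides of the defaults; unknown keys are rejected
#' @return a `run_config` list
#' @export
run_config <- function(...) {
  defaults <- list(
    dt_us = 0.01, dx_um = 1, n_sub = 10L,
    visc_mPas = 0.785, rho_f_kgm3 = 1006, rho_cell_kgm3 = 1050,
    xi_ref = 0.922,
    wall_a = 1e-4, wall_n = 1.2, d_cut_um = 0.1,
    mu_f = 0, flow_rate_uL_h = 22.8,
    variant = "model3", cell_radius_um = 6.5, cell_nodes = 393L,
    viscous_mode = "relative", record_every = 25L, seed = 1L,
    k_s = 0.073, k_b = 1.649, k_al = 0.969, k_ag = 3.084,
    k_V = 0.823, k_visc = 2.481)
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  pos <- c("dt_us", "dx_um", "visc_mPas", "rho_f_kgm3", "rho_cell_kgm3",
           "xi_ref", "wall_n", "d_cut_um", "cell_radius_um")
  for (k in pos) if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0)
    stop("configuration value out of range: ", k, " = ", cfg[[k]])
  if (cfg$mu_f < 0 || cfg$wall_a < 0) stop("negative force coefficient in configuration")
  if (!cfg$variant %in% c("model1", "model2", "model3", "model4"))
    stop("unknown geometry variant: ", cfg$variant)
  invisible(cfg)
}

#' Load a plain-text key = value configuration file
#'
#' Blank lines and `#` comments are ignored. Values parse as numbers
#' where possible, otherwise as strings. Unknown keys, malformed lines
#' and out-of-range values are rejected with the offending line number.
#'
#' @param path configuration file
#' @return a [run_config]
#' @export
load_config <- function(path) {
  lines <- readLines(path)
  over <- list()
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    if (!nzchar(trimws(ln))) next
    m <- regmatches(ln, regexec("^\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(\\S+)\\s*$", ln))[[1]]
    if (length(m) != 3)
      stop("malformed configuration line ", i, ": ", trimws(lines[i]))
    val <- suppressWarnings(as.numeric(m[3]))
    if (is.na(val)) val <- m[3]
    if (grepl("^(n_sub|record_every|seed|cell_nodes)$", m[2])) val <- as.integer(val)
    over[[m[2]]] <- val
  }
  do.call(run_config, over)
}

#' @rdname load_config
#' @param cfg a [run_config] to write
#' @export
write_config <- function(cfg, path) {
  writeLines(vapply(names(cfg), function(k)
    sprintf("%s = %s", k, format(cfg[[k]], digits = 17)), character(1)), path)
  invisible(path)
}
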