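#' Two-stage identification of the cell model parameters
#'
#' Recovers the spring-network parameters of a cell from measured entry
#' and transit times at one or more flow rates. Entry into the
#' constriction is dominated by deformability while transit depends on
#' both deformability and wall friction, so identification proceeds in
#' two stages: first a GA over the six viscoelastic parameters minimising
#' the summed relative entry-time error with friction switched off, then,
#' with those parameters frozen, a one-dimensional GA over the surface
#' friction coefficient for each flow rate separately, minimising that
#' flow rate's relative transit-time error.
#'
#' @param experiments data frame with columns `flow_rate` (uL/h),
#'   `entry_time`, `transit_time` (us)
#' @param sim_factory function `(params, mu_f, flow_rate, stage)`
#'   returning a list with `entry_time` and `transit_time` (us; `NA` or an
#'   error marks a failed/stalled run, which scores `+Inf`); `stage` is
#'   `"entry"` (only the entry time is needed) or `"full"`
#' @param bounds identification bounds, see [ga_bounds]
#' @param config_stage1,config_stage2 [ga_config]s for the two stages;
#'   the defaults stop at error 0.05
#' @param seed RNG seed (stage 2 for flow rate k uses `seed + k`)
#' @return an `identify_result`: `params` ([elastic_params]), `mu_f`
#'   (named per flow rate), the two stage errors and the underlying
#'   [ga_run] results
#' @export
identify_cell <- function(experiments, sim_factory, bounds = ga_bounds(),
                          config_stage1 = ga_config(stop_threshold = 0.05),
                          config_stage2 = ga_config(stop_threshold = 0.05),
                          seed = 1) {
  stopifnot(nrow(experiments) >= 1,
            all(c("flow_rate", "entry_time", "transit_time") %in% names(experiments)))
  visco <- c("k_s", "k_b", "k_al", "k_ag", "k_V", "k_visc")
  b <- bounds[match(visco, bounds$param), ]
  lower <- stats::setNames(b$lower, visco)
  upper <- stats::setNames(b$upper, visco)

  obj1 <- function(p) {
    et <- vapply(experiments$flow_rate, function(fr) {
      r <- sim_factory(p, mu_f = 0, flow_rate = fr, stage = "entry")
      if (is.null(r$entry_time) || !is.finite(r$entry_time)) return(NA_real_)
      r$entry_time
    }, numeric(1))
    if (anyNA(et)) return(Inf)
    error_entry(et, experiments$entry_time)
  }
  stage1 <- ga_run(obj1, lower, upper, config_stage1, seed = seed)
  p1 <- stage1$best_params

  bf <- bounds[bounds$param == "mu_f", ]
  stage2 <- vector("list", nrow(experiments))
  mu_f <- numeric(nrow(experiments))
  err2 <- numeric(nrow(experiments))
  for (k in seq_len(nrow(experiments))) {
    fr <- experiments$flow_rate[k]
    tt_e <- experiments$transit_time[k]
    obj2 <- function(p) {
      r <- sim_factory(p1, mu_f = p[["mu_f"]], flow_rate = fr, stage = "full")
      if (is.null(r$transit_time) || !is.finite(r$transit_time)) return(Inf)
      error_transit(r$transit_time, tt_e)
    }
    stage2[[k]] <- ga_run(obj2, c(mu_f = bf$lower), c(mu_f = bf$upper),
                          config_stage2, seed = seed + k)
    mu_f[k] <- stage2[[k]]$best_params[["mu_f"]]
    err2[k] <- stage2[[k]]$best_error
  }
  structure(list(params = do.call(elastic_params, as.list(p1)),
                 mu_f = stats::setNames(mu_f, experiments$flow_rate),
                 entry_error = stage1$best_error, transit_errors = err2,
                 stage1 = stage1, stage2 = stage2,
                 experiments = experiments),
            class = "identify_result")
}

#' @export
print.identify_result <- function(x, ...) {
  cat("two-stage identification\n  stage 1 (entry, friction off): error",
      signif(x$entry_error, 4), "\n")
  print(round(unlist(x$params), 5))
  cat("  stage 2 (transit) per flow rate:\n")
  for (k in seq_along(x$mu_f))
    cat(sprintf("    %s uL/h: mu_f = %.5f (error %.4f)\n",
                names(x$mu_f)[k], x$mu_f[k], x$transit_errors[k]))
  invisible(x)
}
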