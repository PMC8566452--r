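#' Decode a fractional binary chromosome
#'
#' A parameter is encoded as an n-bit binary fraction
#' `q = sum a_k 2^-(k+1)` mapped affinely onto its bounds:
#' `K = K_L + (K_U - K_L) q`. All-zero bits decode to `K_L` exactly and
#' all-one bits to `K_U` up to `2^-n` of the range.
#'
#' @param bits the chromosome: a 0/1 integer vector, or a string of
#'   `"0"`/`"1"` characters
#' @param lower,upper the parameter bounds `K_L < K_U`
#' @return the decoded parameter value
#' @examples
#' ga_decode(strrep("0", 128), 0.0001, 10) # exactly 0.0001
#' @export
ga_decode <- function(bits, lower, upper) {
  if (is.character(bits)) {
    bits <- suppressWarnings(as.integer(strsplit(bits, "")[[1]]))
    if (anyNA(bits)) stop("chromosome contains non-binary characters")
  }
  if (!all(bits %in% c(0L, 1L))) stop("chromosome contains non-binary values")
  if (lower >= upper) stop("lower bound must be below upper bound")
  q <- sum(bits * 2^(-seq_along(bits)))
  lower + (upper - lower) * q
}

#' Genetic-algorithm configuration
#'
#' @param pop_size chromosomes carried between iterations (default 40)
#' @param candidates distinct parameter sets evaluated per iteration
#'   (default 400), including the injected elites
#' @param elite best sets of the previous iteration injected unchanged
#'   (default 20); elitism makes the best-error history non-increasing
#' @param crossover_threshold,mutation_threshold a uniform draw above the
#'   threshold triggers the operator (so a threshold of 0.8 means rate
#'   0.2): crossover is decided once per parameter, mutation per bit
#' @param n_bits chromosome length per parameter
#' @param stop_threshold stop when the best error falls below this
#' @param stall_iters stop when the best error is unchanged this many
#'   successive iterations (default 20)
#' @param max_iter hard iteration cap
#' @return a `ga_config` list
#' @export
ga_config <- function(pop_size = 40, candidates = 400, elite = 20,
                      crossover_threshold = 0.8, mutation_threshold = 0.8,
                      n_bits = 128, stop_threshold = 1,
                      stall_iters = 20, max_iter = 100) {
  stopifnot(elite < candidates, pop_size >= 2,
            crossover_threshold > 0, crossover_threshold < 1,
            mutation_threshold > 0, mutation_threshold < 1)
  structure(list(pop_size = pop_size, candidates = candidates, elite = elite,
                 crossover_threshold = crossover_threshold,
                 mutation_threshold = mutation_threshold, n_bits = n_bits,
                 stop_threshold = stop_threshold, stall_iters = stall_iters,
                 max_iter = max_iter), class = "ga_config")
}

#' Identification bounds for the spring-network parameters
#'
#' Default lower/upper identification bounds of the seven model
#' quantities (five elastic moduli, membrane viscosity, surface
#' friction).
#'
#' @return a data frame with columns `param`, `lower`, `upper`
#' @export
ga_bounds <- function() {
  data.frame(param = c("k_s", "k_b", "k_al", "k_ag", "k_V", "k_visc", "mu_f"),
             lower = c(1e-4, 1e-4, 1e-4, 0.1, 0.1, 0.1, 1e-4),
             upper = c(10, 10, 10, 10, 10, 10, 1))
}

random_chromosome <- function(npar, n_bits) {
  matrix(as.integer(runif(npar * n_bits) < 0.5), npar, n_bits)
}

decode_chromosome <- function(ch, lower, upper) {
  q <- as.numeric(ch %*% 2^(-seq_len(ncol(ch))))
  lower + (upper - lower) * q
}

vary_chromosome <- function(p1, p2, cfg) {
  child <- p1
  npar <- nrow(p1); nb <- ncol(p1)
  for (k in seq_len(npar)) {
    if (runif(1) > cfg$crossover_threshold) {
      cut <- sample.int(nb - 1L, 1L)
      child[k, ] <- c(p1[k, seq_len(cut)], p2[k, (cut + 1L):nb])
    }
  }
  flip <- matrix(runif(npar * nb) > cfg$mutation_threshold, npar, nb)
  child[flip] <- 1L - child[flip]
  child
}

#' Run the genetic algorithm
#'
#' Minimises `objective` over box-bounded parameters encoded as
#' fractional binary chromosomes. Each iteration evaluates about
#' `candidates` distinct parameter sets generated by tournament
#' selection, per-parameter single-point crossover and per-bit mutation,
#' always injecting the `elite` best sets of the previous iteration
#' unchanged. Stops when the best error drops below `stop_threshold` or
#' has not improved for `stall_iters` iterations. A failing objective
#' (error or non-finite value) scores `+Inf` and the candidate is kept in
#' the books, mirroring crashed simulations. Identical seeds and
#' configurations reproduce bit-identical runs; evaluations are cached by
#' decoded parameter set, so evaluation order cannot affect results.
#'
#' @param objective function of a named parameter vector returning a
#'   scalar error
#' @param lower,upper bound vectors (names taken from `lower` if present)
#' @param config a [ga_config]
#' @param seed RNG seed
#' @return a `ga_result`: `best_params`, `best_error`, `history` tibble
#'   (iteration, best error, cumulative evaluations), `stopped_by`
#' @export
ga_run <- function(objective, lower, upper, config = ga_config(), seed = 1) {
  stopifnot(length(lower) == length(upper), all(lower < upper))
  npar <- length(lower)
  nms <- names(lower)
  if (is.null(nms)) nms <- paste0("p", seq_len(npar))
  set.seed(seed)

  cache <- new.env(hash = TRUE, parent = emptyenv())
  n_evals <- 0L
  evaluate <- function(vals) {
    key <- paste(signif(vals, 15), collapse = "|")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    err <- tryCatch({
      e <- objective(stats::setNames(vals, nms))
      if (!is.finite(e)) Inf else e
    }, error = function(e) Inf)
    n_evals <<- n_evals + 1L
    cache[[key]] <- err
    err
  }

  pop <- replicate(config$pop_size, random_chromosome(npar, config$n_bits),
                   simplify = FALSE)
  pop_err <- rep(NA_real_, config$pop_size)
  elites <- list()
  best_err <- Inf
  best_ch <- NULL
  history <- NULL
  stall <- 0L
  stopped_by <- "max_iter"

  chrom_key <- function(ch)
    paste(signif(decode_chromosome(ch, lower, upper), 15), collapse = "|")
  tournament <- function() {
    ij <- sample.int(length(pop), 2L)
    if (pop_err[ij[1]] <= pop_err[ij[2]]) pop[[ij[1]]] else pop[[ij[2]]]
  }

  for (iter in seq_len(config$max_iter)) {
    if (anyNA(pop_err))
      pop_err <- vapply(pop, function(ch)
        evaluate(decode_chromosome(ch, lower, upper)), numeric(1))
    cands <- c(elites, pop)
    keys <- vapply(cands, chrom_key, character(1))
    cands <- cands[!duplicated(keys)]
    keys <- keys[!duplicated(keys)]
    attempts <- 0L
    while (length(cands) < config$candidates &&
           attempts < 50L * config$candidates) {
      ch <- vary_chromosome(tournament(), tournament(), config)
      key <- chrom_key(ch)
      attempts <- attempts + 1L
      if (!key %in% keys) { cands[[length(cands) + 1L]] <- ch; keys <- c(keys, key) }
    }
    errs <- vapply(cands, function(ch)
      evaluate(decode_chromosome(ch, lower, upper)), numeric(1))
    ord <- order(errs)
    cands <- cands[ord]; errs <- errs[ord]

    if (errs[1] < best_err) { best_err <- errs[1]; best_ch <- cands[[1]]; stall <- 0L }
    else stall <- stall + 1L
    history <- rbind(history, data.frame(iteration = iter, best_error = best_err,
                                         evaluations = n_evals))

    if (is.finite(config$stop_threshold) && best_err < config$stop_threshold) {
      stopped_by <- "threshold"; break
    }
    if (stall >= config$stall_iters) { stopped_by <- "stall"; break }

    elites <- cands[seq_len(min(config$elite, length(cands)))]
    keep <- seq_len(min(config$pop_size, length(cands)))
    pop <- cands[keep]
    pop_err <- errs[keep]
  }

  structure(list(best_params = stats::setNames(decode_chromosome(best_ch, lower, upper), nms),
                 best_error = best_err, best_chromosome = best_ch,
                 history = tibble::as_tibble(history),
                 n_evaluations = n_evals, stopped_by = stopped_by,
                 seed = seed, config = config),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat("GA result: best error", signif(x$best_error, 4), "after",
      nrow(x$history), "iterations (", x$n_evaluations, "evaluations),",
      "stopped by", x$stopped_by, "\n")
  print(round(x$best_params, 5))
  invisible(x)
}

#' Error functions for parameter identification
#'
#' `error_stretch` is the summed squared deviation of axial and
#' transverse diameters over matched force points,
#' `sum((s_a - e_a)^2 + (s_t - e_t)^2)`. `error_entry` sums the relative
#' entry-time mismatch `|1 - ET_sim / ET_exp|` over flow rates, and
#' `error_transit` is the per-experiment relative transit-time mismatch
#' `|1 - TT_sim / TT_exp|`.
#'
#' @param sim,exp for `error_stretch`: data frames with columns `axial`
#'   and `transverse`, matched row for row
#' @return a non-negative scalar (`error_transit` vectorises over
#'   experiments)
#' @export
error_stretch <- function(sim, exp) {
  if (nrow(sim) != nrow(exp)) stop("simulated and experimental tables differ in length")
  sum((sim$axial - exp$axial)^2 + (sim$transverse - exp$transverse)^2)
}

#' @rdname error_stretch
#' @param et_sim,et_exp entry times (us), matched by flow rate
#' @export
error_entry <- function(et_sim, et_exp) {
  if (length(et_sim) != length(et_exp)) stop("entry-time vectors differ in length")
  if (any(et_exp == 0)) stop("experimental entry time of zero")
  sum(abs(1 - et_sim / et_exp))
}

#' @rdname error_stretch
#' @param tt_sim,tt_exp transit times (us) for one experiment each
#' @export
error_transit <- function(tt_sim, tt_exp) {
  if (any(tt_exp == 0)) stop("experimental transit time of zero")
  abs(1 - tt_sim / tt_exp)
}
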