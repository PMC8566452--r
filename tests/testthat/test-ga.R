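ga_worked_example <- paste0(
  "0111111111011010101010001000110111100100111100100011101101111011",
  "0101011010101010000100001101010110110110101001001111000000110110")

test_that("the 128-bit fractional decode matches the worked example and bounds", {
  expect_equal(nchar(ga_worked_example), 128L)
  expect_equal(round(ga_decode(ga_worked_example, 0.0001, 10), 3), 4.994)
  expect_identical(ga_decode(strrep("0", 128), 0.0001, 10), 0.0001)
  expect_equal(ga_decode(strrep("1", 128), 0.0001, 10),
               10 - (10 - 0.0001) * 2^-128, tolerance = 1e-15)
  expect_error(ga_decode("01x1", 0, 1), "non-binary")
  expect_error(ga_decode("0101", 2, 1), "bound")
})

test_that("decode is monotone in the chromosome read as an integer and stays in bounds", {
  set.seed(31)
  vals <- replicate(50, {
    bits <- as.integer(runif(32) < 0.5)
    c(int = sum(bits * 2^(31:0)), val = ga_decode(bits, -2, 7))
  })
  o <- order(vals["int", ])
  expect_true(all(diff(vals["val", o]) >= 0))
  expect_true(all(vals["val", ] >= -2 & vals["val", ] <= 7))
})

test_that("the stretch error is the summed squared diameter deviation", {
  tab <- data.frame(axial = c(8, 9, 10), transverse = c(7, 6.5, 6))
  expect_identical(error_stretch(tab, tab), 0)
  sim <- data.frame(axial = 9, transverse = 8)
  exp_ <- data.frame(axial = 8, transverse = 6)
  expect_identical(error_stretch(sim, exp_), 5)      # 1^2 + 2^2
  set.seed(5)
  a <- data.frame(axial = rnorm(12), transverse = rnorm(12))
  b <- data.frame(axial = rnorm(12), transverse = rnorm(12))
  expect_equal(error_stretch(a, b),
               sum((a$axial - b$axial)^2) + sum((a$transverse - b$transverse)^2),
               tolerance = 1e-12)
  expect_error(error_stretch(a, b[1:3, ]), "length")
})

test_that("entry and transit errors reproduce the published-table values", {
  # calculated entry times at the two flow rates against the measured ones
  expect_equal(round(error_entry(c(16595, 2094), c(17540, 2470)), 3), 0.206)
  expect_equal(round(error_transit(532, 526), 3), 0.011)
  expect_identical(error_entry(c(100, 200), c(100, 200)), 0)
  expect_equal(error_entry(90, 100), 0.1, tolerance = 1e-14)
  expect_identical(error_transit(150, 150), 0)
  expect_equal(error_transit(1.5 * 37, 37), 0.5, tolerance = 1e-12)
  expect_error(error_entry(1, 0), "zero")
  expect_error(error_transit(1, 0), "zero")
})

test_that("error functions are non-negative and scale-invariant", {
  set.seed(8)
  et_s <- runif(4, 50, 150); et_e <- runif(4, 50, 150)
  expect_gte(error_entry(et_s, et_e), 0)
  expect_equal(error_entry(3.7 * et_s, 3.7 * et_e), error_entry(et_s, et_e),
               tolerance = 1e-12)
  expect_equal(error_transit(3.7 * et_s[1], 3.7 * et_e[1]),
               error_transit(et_s[1], et_e[1]), tolerance = 1e-12)
})

test_that("the GA recovers a known quadratic optimum on 3 parameters", {
  K_star <- c(p1 = 2.5, p2 = 7.25, p3 = 0.8)
  objective <- function(p) sum((p - K_star)^2)
  cfg <- ga_config(stop_threshold = -Inf, stall_iters = 30, max_iter = 30)
  for (seed in 1:5) {
    res <- ga_run(objective, lower = c(p1 = 0, p2 = 0, p3 = 0),
                  upper = c(p1 = 10, p2 = 10, p3 = 10), cfg, seed = seed)
    expect_true(all(abs(res$best_params - K_star) < 0.1))  # 1% of the range
    expect_lte(nrow(res$history), 30)
    expect_true(all(diff(res$history$best_error) <= 0))
  }
})

test_that("the GA run is bit-reproducible and stops on stalls", {
  objective <- function(p) sum(p^2)
  cfg <- ga_config(pop_size = 10, candidates = 20, elite = 5,
                   stop_threshold = -Inf, stall_iters = 5, max_iter = 50)
  r1 <- ga_run(objective, c(a = -1, b = -1), c(a = 1, b = 1), cfg, seed = 99)
  r2 <- ga_run(objective, c(a = -1, b = -1), c(a = 1, b = 1), cfg, seed = 99)
  expect_identical(r1$best_params, r2$best_params)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$best_chromosome, r2$best_chromosome)
})

test_that("stopping rules trigger on threshold and on 20 unchanged iterations", {
  # flat objective: best error can never improve, so the stall rule fires
  cfg <- ga_config(pop_size = 8, candidates = 16, elite = 4,
                   stop_threshold = -Inf, stall_iters = 20, max_iter = 100)
  res <- ga_run(function(p) 1, c(x = 0), c(x = 1), cfg, seed = 4)
  expect_identical(res$stopped_by, "stall")
  expect_lte(nrow(res$history), 21)
  # threshold rule
  cfg2 <- ga_config(pop_size = 8, candidates = 16, elite = 4,
                    stop_threshold = 10, max_iter = 100)
  res2 <- ga_run(function(p) 1, c(x = 0), c(x = 1), cfg2, seed = 4)
  expect_identical(res2$stopped_by, "threshold")
  expect_identical(nrow(res2$history), 1L)
})

test_that("failing objective evaluations score +Inf without aborting the run", {
  objective <- function(p) {
    if (p[["x"]] > 0.5) stop("simulation crashed")
    p[["x"]]
  }
  cfg <- ga_config(pop_size = 10, candidates = 20, elite = 5,
                   stop_threshold = -Inf, stall_iters = 5, max_iter = 20)
  res <- ga_run(objective, c(x = 0), c(x = 1), cfg, seed = 7)
  expect_lt(res$best_error, 0.5)
  expect_true(is.finite(res$best_error))
})
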