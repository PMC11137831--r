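test_that("association constants convert to free energies and back", {
  expect_equal(ka_to_dg(1), 0)
  # -RT ln(10) at 298 K with R = 1.9872e-3
  expect_equal(ka_to_dg(10, 298), -1.9872e-3 * 298 * log(10))
  expect_equal(round(ka_to_dg(10, 298), 4), -1.3636)
  for (ka in c(1e-3, 2.5, 1e6))
    expect_equal(dg_to_ka(ka_to_dg(ka)), ka, tolerance = 1e-12)
  expect_error(ka_to_dg(0), "positive")
  expect_error(ka_to_dg(-2), "positive")
})

test_that("replicate aggregation reproduces the published table cells", {
  # five metal-phosphate rows: printed Average +/- std at 2 decimals
  rows <- list(
    list(reps = c(-1.89, -1.97, -2.02), mean = -1.96, std = 0.07),
    list(reps = c(-3.54, -3.47, -3.61), mean = -3.54, std = 0.07),
    list(reps = c(-8.69, -8.34, -8.56), mean = -8.53, std = 0.18),
    list(reps = c(-1.75, -1.65, -1.73), mean = -1.71, std = 0.05),
    list(reps = c(-3.63, -3.52, -3.49), mean = -3.55, std = 0.07))
  for (row in rows) {
    a <- aggregate_replicates(row$reps)
    expect_equal(round(a$mean, 2), row$mean)
    expect_equal(round(a$std, 2), row$std)
  }
  expect_equal(format_replicates(c(-1.89, -1.97, -2.02)), "-1.96 ± 0.07")
  expect_equal(aggregate_replicates(c(2.2, 2.2, 2.2))$std, 0)
  expect_error(aggregate_replicates(1.5), "at least 2")
})

test_that("replicate statistics agree with a brute-force two-pass formula", {
  set.seed(31)
  for (i in 1:5) {
    v <- rnorm(sample(3:10, 1), sd = 2)
    a <- aggregate_replicates(v)
    m <- sum(v) / length(v)
    s <- sqrt(sum((v - m)^2) / (length(v) - 1))
    expect_equal(a$mean, m, tolerance = 1e-12)
    expect_equal(a$std, s, tolerance = 1e-12)
  }
})

test_that("regression lines interpolate, extrapolate and reject degeneracy", {
  # two points: exact interpolation
  l2 <- fit_regression(c(1, 3), c(2, 8))
  expect_equal(extrapolate(l2, c(1, 3)), c(2, 8), tolerance = 1e-12)
  # a line with the published extrapolation coefficients evaluated at 0
  # returns its intercept
  x <- c(-120, -300, -600)
  l <- fit_regression(x, 1.0763 * x - 22.984)
  expect_equal(l$slope, 1.0763, tolerance = 1e-10)
  expect_equal(extrapolate(l, 0), -22.984, tolerance = 1e-9)
  # colinear five-point set: zero residuals
  x5 <- 1:5
  l5 <- fit_regression(x5, 2.5 * x5 + 1)
  expect_lt(max(abs(extrapolate(l5, x5) - (2.5 * x5 + 1))), 1e-10)
  expect_error(fit_regression(c(2, 2, 2), 1:3), "degenerate")
})

test_that("bisection fitting inverts an analytic monotone objective", {
  # noise-free objective dG(C4) = -2 - 0.01*C4 (seed is ignored)
  obj <- function(C4, seed) -2 - 0.01 * C4
  tgt <- fit_target(-3.1, "binding_pmf", tolerance = 0.001)
  fit <- fit_c4(NULL, tgt, c(0, 400), seeds = 1:3, objective = obj)
  expect_lt(abs(fit$C4_fit - 110) / 110, 0.02)
  expect_lte(abs(fit$mean - tgt$target_dG), tgt$tolerance)
  # a target sitting exactly at the bracket midpoint converges at once
  tgt_mid <- fit_target(obj(200, 1), "binding_pmf", tolerance = 1e-9)
  fit_mid <- fit_c4(NULL, tgt_mid, c(0, 400), seeds = 1L,
                    objective = obj)
  expect_equal(fit_mid$C4_fit, 200)
  # both bracket ends above the target: bracketing error
  expect_error(
    fit_c4(NULL, fit_target(-99, "binding_pmf"), c(0, 400), seeds = 1L,
           objective = obj),
    "bracket")
  # non-monotone objective is rejected before bisection
  expect_error(
    fit_c4(NULL, fit_target(-1, "binding_pmf"), c(-1, 1), seeds = 1L,
           objective = function(C4, seed) (C4 - 0.5)^2),
    "monotone")
})

test_that("fitting is invariant to a joint shift of target and objective", {
  base <- function(C4, seed) -1 - 0.02 * C4
  for (delta in c(0, 5)) {
    obj <- function(C4, seed) base(C4, seed) - delta
    fit <- fit_c4(NULL, fit_target(-4 - delta, "binding_pmf",
                                   tolerance = 1e-6),
                  c(0, 300), seeds = 1L, objective = obj)
    expect_equal(fit$C4_fit, 150, tolerance = 1e-3)
  }
})

test_that("an unreachable tolerance reports the achievable precision", {
  obj <- function(C4, seed) -2 # flat: cannot approach the target
  expect_error(
    fit_c4(NULL, fit_target(-5, "binding_pmf"), c(0, 100), seeds = 1L,
           objective = obj),
    "flat")
  # monotone but quantized objective cannot reach a tiny tolerance
  obj_q <- function(C4, seed) -round(C4) * 0.1
  expect_error(
    fit_c4(NULL, fit_target(-1.55, "binding_pmf", tolerance = 1e-6),
           c(0, 100), seeds = 1L, objective = obj_q),
    "noise floor")
})

test_that("a planted C4 is recovered through the binding pipeline", {
  sys <- toy_system("ion_pair_continuum")
  cfg <- quick_cfg(2.5e4, seed = 1)
  obj <- binding_objective(sys, cfg)
  seeds <- c(101L, 202L, 303L)
  c4_star <- 80
  planted <- mean(vapply(seeds, function(s) obj(c4_star, s), numeric(1)))
  fit <- fit_c4(sys, fit_target(planted, "binding_pmf"), c(-250, 250),
                seeds, cfg)
  expect_lte(abs(fit$mean - planted), 0.30)
  # slope from the scan converts the dG tolerance into a C4 band
  slope <- abs(diff(range(fit$scan$mean_dG)) / diff(range(fit$scan$C4)))
  expect_lt(abs(fit$C4_fit - c4_star), 0.30 / slope + 1)
  expect_equal(length(fit$replicate_values), 3)
  expect_false(is.na(fit$std))
})

test_that("the packaged experimental target table is well formed", {
  tg <- packaged_targets()
  expect_named(tg, c("species", "metal", "observable", "target_dG",
                     "tolerance"))
  expect_true(all(tg$observable %in% c("hfe_ti", "binding_pmf")))
  expect_true(all(tg$tolerance > 0))
  expect_true(all(tg$target_dG < 0))
  # binding rows carry the coarser tolerance of the PMF route
  expect_true(all(tg$tolerance[tg$observable == "binding_pmf"] == 0.30))
  expect_true(all(tg$tolerance[tg$observable == "hfe_ti"] == 0.05))
})
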