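# Fitting C4 cross-terms against target free energies: association
# constant conversion, replicate aggregation, bisection fitting with
# common random numbers, and the linear-regression extrapolation used for
# missing experimental hydration free energies.

#' Convert an association constant to a binding free energy
#'
#' Delta G = -R T ln(Ka), R = 1.9872e-3 kcal/(mol*K). Experimental binding
#' targets are usually reported as Ka at 298 K.
#'
#' @param Ka Association constant (> 0).
#' @param T Temperature, K (default 298).
#' @return Delta G, kcal/mol.
#' @export
ka_to_dg <- function(Ka, T = 298) {
  if (any(Ka <= 0)) stop("Ka must be positive")
  if (T <= 0) stop("temperature must be positive")
  -R_GAS * T * log(Ka)
}

#' Inverse of [ka_to_dg()]
#' @param dG Binding free energy, kcal/mol.
#' @param T Temperature, K.
#' @return Ka.
#' @export
dg_to_ka <- function(dG, T = 298) exp(-dG / (R_GAS * T))

#' Aggregate replicate free energies
#'
#' Arithmetic mean and sample (n - 1) standard deviation of independent
#' replicate runs, the "Rep #1..#3, Average +/- std" convention. Rounding
#' to 2 decimals is presentation only (see [format_replicates()]).
#'
#' @param values Numeric vector of replicate Delta G values (>= 2).
#' @return List with `mean` and `std`.
#' @export
aggregate_replicates <- function(values) {
  if (length(values) < 2)
    stop("replicate aggregation needs at least 2 values")
  list(mean = mean(values), std = sd(values))
}

#' Format replicate statistics the way result tables print them
#' @param values Numeric vector of replicate Delta G values.
#' @return String "mean +/- std" rounded to 2 decimals.
#' @export
format_replicates <- function(values) {
  a <- aggregate_replicates(values)
  sprintf("%.2f ± %.2f", a$mean, a$std)
}

#' Fitting target
#'
#' @param target_dG Target free energy, kcal/mol.
#' @param observable "hfe_ti" (hydration free energy by TI) or
#'   "binding_pmf" (binding free energy from an umbrella-sampling PMF).
#' @param tolerance Acceptance half-width on the replicate mean, kcal/mol;
#'   defaults to 0.05 for hfe_ti and 0.30 for binding_pmf, the agreement
#'   levels the two observables support.
#' @param temperature Temperature, K.
#' @return An object of class `fit_target`.
#' @export
fit_target <- function(target_dG, observable = c("hfe_ti", "binding_pmf"),
                       tolerance = NULL, temperature = 300) {
  observable <- match.arg(observable)
  if (is.null(tolerance))
    tolerance <- if (observable == "hfe_ti") 0.05 else 0.30
  stopifnot(tolerance > 0)
  structure(list(target_dG = target_dG, observable = observable,
                 tolerance = tolerance, temperature = temperature),
            class = "fit_target")
}

#' Binding free-energy objective on the ion-pair toy
#'
#' Builds the function Delta G_bind(C4, seed): run umbrella windows over
#' `r_range`, solve WHAM, and read the well-minus-plateau binding free
#' energy. Used by [fit_c4()] for `binding_pmf` targets.
#'
#' @param system An `ion_pair_continuum` [toy_system()] (its `C4` is
#'   overridden at each evaluation).
#' @param cfg A [sampler_config()]; its seed is replaced per evaluation.
#' @param r_range Windowed coordinate range, A.
#' @param spacing Window spacing, A (default 0.5).
#' @param k_rest Restraint constant, kcal/(mol*A^2).
#' @param bound_max_r Outer edge of the bound region, A.
#' @param wham A [wham_config()].
#' @return Function of (C4, seed) returning Delta G_bind.
#' @export
binding_objective <- function(system, cfg, r_range = c(2, 11),
                              spacing = 0.5, k_rest = 10, bound_max_r = 5,
                              wham = NULL) {
  stopifnot(system$kind == "ion_pair_continuum")
  if (is.null(wham)) wham <- wham_config(temperature = cfg$temperature)
  restraints <- plan_windows(r_range[1], r_range[2], spacing, k_rest)
  function(C4, seed) {
    sys_i <- system
    sys_i$pars$C4 <- C4
    cfg_i <- cfg
    cfg_i$seed <- as.integer(seed)
    wins <- run_us(sys_i, restraints, cfg_i)
    pmf <- wham_solve(wins, wham)
    as.numeric(binding_dg_from_pmf(pmf, bound_max_r))
  }
}

#' Hydration free-energy objective on the micro-solvation toy
#'
#' Builds the function Delta G_HFE(C4, seed): run the TI cycle with the
#' requested protocol at solute-solvent C4 and return its total free
#' energy. Used by [fit_c4()] for `hfe_ti` targets.
#'
#' @param system A `micro_solvation_box` [toy_system()].
#' @param cfg A [sampler_config()] (per-node chain length etc.).
#' @param schedule A [gauss_legendre_unit()] schedule (default order 12).
#' @param protocol "one_step" or "two_step".
#' @return Function of (C4, seed) returning Delta G_HFE.
#' @export
hfe_objective <- function(system, cfg, schedule = gauss_legendre_unit(12),
                          protocol = "one_step") {
  stopifnot(system$kind == "micro_solvation_box")
  path <- alchemical_path(protocol)
  function(C4, seed) {
    sys_i <- system
    sys_i$pars$C4_us <- C4
    cfg_i <- cfg
    cfg_i$seed <- as.integer(seed)
    run_hfe_cycle(sys_i, path, schedule, cfg_i)$delta_G
  }
}

#' Fit a C4 cross-term against a target free energy
#'
#' Bisection on C4 with common random numbers: each candidate C4 is
#' evaluated with the same fixed replicate seeds, so the objective is a
#' deterministic function of C4 and bisection on a monotone objective is
#' well posed. Before bisecting, the objective is scanned at 5 points
#' across the bracket and required to be monotone within noise (3x the
#' replicate standard error), protecting the implicit monotonicity
#' assumption; the bracket must straddle the target. The fit succeeds when
#' the replicate-mean free energy is within `target$tolerance` of the
#' target.
#'
#' @param system A [toy_system()] matching `target$observable`
#'   (`ion_pair_continuum` for binding, `micro_solvation_box` for HFE).
#'   Ignored when `objective` is supplied.
#' @param target A [fit_target()].
#' @param bracket `c(C4_low, C4_high)`, kcal*A^4/mol.
#' @param seeds Integer vector of replicate seeds (3 by convention).
#' @param cfg A [sampler_config()] passed to the pipeline objective.
#' @param objective Optional function (C4, seed) -> Delta G overriding the
#'   built-in pipelines (used with analytic objectives).
#' @param max_iterations Bisection cap (default 60).
#' @param ... Passed to [binding_objective()] / [hfe_objective()].
#' @return An object of class `fit_result`: `C4_fit`, `achieved_dG`,
#'   `replicate_values`, `mean`, `std`, `n_evaluations`, `bracket`,
#'   `scan` (the pre-scan table).
#' @export
fit_c4 <- function(system, target, bracket, seeds, cfg = NULL,
                   objective = NULL, max_iterations = 60, ...) {
  stopifnot(inherits(target, "fit_target"), length(bracket) == 2,
            bracket[1] < bracket[2], length(seeds) >= 1)
  if (is.null(objective)) {
    objective <- switch(target$observable,
      binding_pmf = binding_objective(system, cfg, ...),
      hfe_ti = hfe_objective(system, cfg, ...))
  }
  n_eval <- 0L
  eval_reps <- function(C4) {
    n_eval <<- n_eval + length(seeds)
    vapply(seeds, function(s) objective(C4, s), numeric(1))
  }
  # 5-point monotonicity scan across the bracket
  xs <- seq(bracket[1], bracket[2], length.out = 5)
  reps <- lapply(xs, eval_reps)
  ms <- vapply(reps, mean, numeric(1))
  noise <- if (length(seeds) > 1)
    max(vapply(reps, function(v) sd(v) / sqrt(length(v)), numeric(1)))
  else 0
  dirn <- sign(ms[5] - ms[1])
  if (dirn == 0) stop("objective is flat across the bracket")
  viol <- diff(ms) * dirn < -3 * noise - 1e-12
  if (any(viol))
    stop("objective is not monotone within noise across the bracket")
  g_lo <- ms[1]
  g_hi <- ms[5]
  if ((g_lo - target$target_dG) * (g_hi - target$target_dG) > 0)
    stop(sprintf(paste0("bracketing error: objective spans [%.3f, %.3f] ",
                        "kcal/mol and does not straddle the target %.3f"),
                 min(g_lo, g_hi), max(g_lo, g_hi), target$target_dG))
  lo <- bracket[1]
  hi <- bracket[2]
  best <- list(C4 = NA_real_, reps = NULL, gap = Inf)
  # reuse scan endpoints already within tolerance
  for (i in c(1L, 5L)) {
    gap <- abs(ms[i] - target$target_dG)
    if (gap < best$gap) best <- list(C4 = xs[i], reps = reps[[i]],
                                     gap = gap)
  }
  for (it in seq_len(max_iterations)) {
    if (best$gap <= target$tolerance) break
    mid <- (lo + hi) / 2
    r_mid <- eval_reps(mid)
    m_mid <- mean(r_mid)
    gap <- abs(m_mid - target$target_dG)
    if (gap < best$gap) best <- list(C4 = mid, reps = r_mid, gap = gap)
    if (gap <= target$tolerance) break
    if ((m_mid - target$target_dG) * dirn < 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-9 * max(1, abs(bracket[2] - bracket[1]))) break
  }
  if (best$gap > target$tolerance)
    stop(sprintf(paste0("tolerance %.3f kcal/mol unreachable at the ",
                        "noise floor; achievable |mean - target| = %.3f"),
                 target$tolerance, best$gap))
  structure(list(C4_fit = best$C4, achieved_dG = mean(best$reps),
                 replicate_values = best$reps, mean = mean(best$reps),
                 std = if (length(best$reps) > 1) sd(best$reps) else
                   NA_real_,
                 n_evaluations = n_eval, bracket = bracket,
                 scan = data.frame(C4 = xs, mean_dG = ms)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> C4 = %.2f kcal*A^4/mol, Delta G = %s",
              x$C4_fit, format_replicates(
                if (length(x$replicate_values) > 1) x$replicate_values
                else rep(x$achieved_dG, 2))),
      sprintf("(%d evaluations)\n", x$n_evaluations))
  invisible(x)
}

#' Ordinary least-squares line through calibration points
#'
#' Used to extrapolate a missing experimental hydration free energy from
#' the species whose computed and experimental values are both known. With
#' exactly two points the line interpolates both exactly.
#'
#' @param x,y Numeric vectors (>= 2 points, non-degenerate x spread).
#' @return An object of class `regression_line`: `slope`, `intercept`,
#'   `points`.
#' @export
fit_regression <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (diff(range(x)) == 0) stop("degenerate fit: all x values equal")
  fit <- lm(y ~ x)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 points = data.frame(x = x, y = y)),
            class = "regression_line")
}

#' Evaluate a regression line (extrapolation = line evaluation)
#' @param line A [fit_regression()] result.
#' @param x Abscissa(e) at which to evaluate.
#' @return Predicted y.
#' @export
extrapolate <- function(line, x) {
  stopifnot(inherits(line, "regression_line"))
  line$slope * x + line$intercept
}

#' @export
print.regression_line <- function(x, ...) {
  cat(sprintf("<regression_line> y = %.4f x %+.3f (%d points)\n",
              x$slope, x$intercept, nrow(x$points)))
  invisible(x)
}
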