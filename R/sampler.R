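# Canonical-ensemble Metropolis Monte Carlo over the toy systems, with
# optional harmonic restraints (umbrella biases) and lambda-coupled
# alchemical paths. MC rather than MD: every observable handled here (free
# energies, PMFs) depends only on the equilibrium distribution, and a
# Metropolis chain is exactly seedable.

#' Sampler configuration
#'
#' @param n_steps Total Metropolis steps (proposals).
#' @param temperature Temperature, K (default 300).
#' @param step_size Proposal half-width, A; `NULL` uses the system default.
#' @param seed Integer RNG seed; identical seed and configuration give
#'   bit-identical output.
#' @param burn_in Steps discarded before recording; default 10\% of
#'   `n_steps`.
#' @param thin Record every `thin`-th post-burn-in step (default 10).
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(n_steps, temperature = 300, step_size = NULL,
                           seed = 1L, burn_in = NULL, thin = 10L) {
  if (is.null(burn_in)) burn_in <- floor(n_steps / 10)
  stopifnot(temperature > 0, n_steps > burn_in, burn_in >= 0, thin >= 1)
  structure(list(n_steps = as.integer(n_steps), temperature = temperature,
                 step_size = step_size, seed = as.integer(seed),
                 burn_in = as.integer(burn_in), thin = as.integer(thin)),
            class = "sampler_config")
}

#' Harmonic restraint (umbrella bias)
#'
#' Bias potential k_rest (r - r0)^2 / 2 on the pair-distance coordinate.
#'
#' @param k_rest Force constant, kcal/(mol*A^2) (> 0).
#' @param r0 Restraint center, A (>= 0).
#' @return An object of class `restraint_spec`.
#' @export
restraint_spec <- function(k_rest, r0) {
  stopifnot(k_rest > 0, r0 >= 0)
  structure(list(k_rest = k_rest, r0 = r0), class = "restraint_spec")
}

new_time_series <- function(values, acceptance, meta) {
  structure(list(values = as.numeric(values), acceptance = acceptance,
                 meta = meta), class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> n = %d, acceptance = %.3f\n",
              length(x$values), x$acceptance))
  invisible(x)
}

#' Draw canonical-ensemble samples from a toy system
#'
#' Metropolis chain targeting exp(-(U + U_bias)/k_B T). For 1-d systems the
#' recorded observable is the coordinate itself; for the micro-solvation
#' box it is the distance from the solute to its nearest solvent bead.
#'
#' @param system A [toy_system()].
#' @param cfg A [sampler_config()].
#' @param bias Optional [restraint_spec()] (1-d systems only).
#' @return A `time_series` with `values`, `acceptance`, and `meta`
#'   (seed, temperature, restraint).
#' @export
sample_canonical <- function(system, cfg, bias = NULL) {
  stopifnot(inherits(system, "toy_system"), inherits(cfg, "sampler_config"))
  step <- if (is.null(cfg$step_size)) system$pars$step else cfg$step_size
  set.seed(cfg$seed)
  if (system$kind == "micro_solvation_box") {
    if (!is.null(bias)) stop("restraints are supported on 1-d systems only")
    res <- run_box(system, cfg, step,
                   lam = c(1, 1, 1), shared_sc = FALSE)
    return(new_time_series(res$obs, res$acceptance,
                           list(seed = cfg$seed,
                                temperature = cfg$temperature)))
  }
  p <- system$pars
  bk <- if (is.null(bias)) -1 else bias$k_rest
  br <- if (is.null(bias)) 0 else bias$r0
  res <- mc1d_cpp(KIND_CODES[[system$kind]], pars_vector_1d(system),
                  init_coord_1d(system), cfg$temperature, cfg$n_steps, step,
                  cfg$burn_in, cfg$thin, bk, br, p$domain[1], p$domain[2])
  new_time_series(res$values, res$acceptance,
                  list(seed = cfg$seed, temperature = cfg$temperature,
                       restraint = bias))
}

#' Linear alchemical mixing path between two 1-d systems
#'
#' U(lambda) = (1 - lambda) U_A + lambda U_B; dU/dlambda = U_B - U_A is
#' evaluated analytically at the sampled states.
#'
#' @param system_a,system_b 1-d [toy_system()] objects (endpoint states).
#' @return An object of class `mix_path`.
#' @export
mix_path <- function(system_a, system_b) {
  stopifnot(is_1d_system(system_a), is_1d_system(system_b),
            system_a$kind != "micro_solvation_box")
  structure(list(A = system_a, B = system_b), class = "mix_path")
}

#' Generic functional alchemical path
#'
#' For paths without an analytic dU/dlambda: supply U(x, lambda) and the
#' derivative is taken by central difference in lambda (h = 1e-4) at the
#' sampled states.
#'
#' @param U Function of (x, lambda) returning kcal/mol.
#' @param domain Sampling domain `c(lo, hi)`, A.
#' @param init Initial coordinate.
#' @param step Proposal half-width, A.
#' @return An object of class `fn_path`.
#' @export
fn_path <- function(U, domain, init = mean(domain), step = 0.5) {
  stopifnot(is.function(U))
  structure(list(U = U, domain = domain, init = init, step = step),
            class = "fn_path")
}

#' Sample dU/dlambda along an alchemical path
#'
#' Draws from the mixed ensemble at the given lambda and records the
#' lambda-derivative of the potential at each retained state: analytically
#' for [mix_path()] (linear mixing) and for the decoupling legs of
#' [alchemical_path()] on the micro-solvation box, by central difference
#' (h = 1e-4) for [fn_path()].
#'
#' @param system A [toy_system()] (ignored for `fn_path`).
#' @param path A [mix_path()], [fn_path()], or a decoupling leg produced by
#'   [leg_spec()].
#' @param lambda_value Coupling parameter in `[0, 1]`.
#' @param cfg A [sampler_config()].
#' @return A `time_series` of dU/dlambda values (kcal/mol).
#' @export
sample_dudl <- function(system, path, lambda_value, cfg) {
  if (lambda_value < 0 || lambda_value > 1)
    stop("lambda must lie in [0, 1]")
  stopifnot(inherits(cfg, "sampler_config"))
  set.seed(cfg$seed)
  if (inherits(path, "mix_path")) {
    pa <- path$A$pars
    res <- mc1d_dudl_cpp(KIND_CODES[[path$A$kind]], pars_vector_1d(path$A),
                         KIND_CODES[[path$B$kind]], pars_vector_1d(path$B),
                         lambda_value, init_coord_1d(path$A),
                         cfg$temperature, cfg$n_steps,
                         if (is.null(cfg$step_size)) pa$step else
                           cfg$step_size,
                         cfg$burn_in, cfg$thin, pa$domain[1], pa$domain[2])
    return(new_time_series(res$values, res$acceptance,
                           list(seed = cfg$seed, lambda = lambda_value)))
  }
  if (inherits(path, "fn_path")) {
    res <- mc_fn_dudl(path, lambda_value, cfg)
    return(new_time_series(res$values, res$acceptance,
                           list(seed = cfg$seed, lambda = lambda_value)))
  }
  if (inherits(path, "leg_spec")) {
    stopifnot(system$kind == "micro_solvation_box")
    lam <- leg_lambdas(path$component, lambda_value)
    step <- if (is.null(cfg$step_size)) system$pars$step else cfg$step_size
    res <- run_box(system, cfg, step, lam = lam,
                   shared_sc = identical(path$component, "total"))
    d <- switch(path$component,
                total = res$dudl_vdw + res$dudl_pol + res$dudl_ele,
                vdW = res$dudl_vdw, Pol = res$dudl_pol, Ele = res$dudl_ele)
    return(new_time_series(d, res$acceptance,
                           list(seed = cfg$seed, lambda = lambda_value,
                                component = path$component)))
  }
  stop("unsupported path object")
}

# lambda state of each alchemical component for one leg at coupling l.
# Leg order for the two-step protocol: vdW grows first (soft core, charges
# and C4 off), then Pol (C4), then Ele (charges), avoiding bare-charge
# singularities.
leg_lambdas <- function(component, l) {
  switch(component,
    total = c(l, l, l),
    vdW = c(l, 0, 0),
    Pol = c(1, l, 0),
    Ele = c(1, 1, l),
    stop("unknown leg component: ", component)
  )
}

run_box <- function(system, cfg, step, lam, shared_sc) {
  p <- system$pars
  ss <- box_c12c6_ss(system)
  mcbox_cpp(box_lattice(p$n_solvent + 1, p$box), box_charges(system),
            ss[["C12"]], ss[["C6"]], p$C12_us, p$C6_us, p$C4_us,
            p$box, p$cutoff, cfg$temperature, lam[1], lam[2], lam[3],
            shared_sc, p$alpha_sc, cfg$n_steps, step, cfg$burn_in, cfg$thin)
}

# plain-R Metropolis for functional paths (small-n oracle comparisons)
mc_fn_dudl <- function(path, lambda, cfg, h = 1e-4) {
  beta <- 1 / (R_GAS * cfg$temperature)
  x <- path$init
  u <- path$U(x, lambda)
  if (!is.finite(u)) stop("non-finite energy at the initial state")
  n_keep <- (cfg$n_steps - cfg$burn_in) %/% cfg$thin
  out <- numeric(n_keep)
  acc <- 0L
  kept <- 0L
  step <- if (is.null(cfg$step_size)) path$step else cfg$step_size
  lo <- max(0, lambda - h)
  hi <- min(1, lambda + h)
  for (s in seq_len(cfg$n_steps)) {
    xp <- x + step * (runif(1) * 2 - 1)
    if (xp >= path$domain[1] && xp <= path$domain[2]) {
      up <- path$U(xp, lambda)
      if (!is.finite(up)) stop("non-finite energy encountered")
      if (up <= u || runif(1) < exp(-beta * (up - u))) {
        x <- xp
        u <- up
        acc <- acc + 1L
      }
    }
    if (s > cfg$burn_in && (s - cfg$burn_in) %% cfg$thin == 0 &&
        kept < n_keep) {
      kept <- kept + 1L
      out[kept] <- (path$U(x, hi) - path$U(x, lo)) / (hi - lo)
    }
  }
  list(values = out, acceptance = acc / cfg$n_steps)
}
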