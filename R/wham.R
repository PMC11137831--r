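# Umbrella sampling along a distance coordinate and WHAM reconstruction of
# the potential of mean force, plus binding free energies and landmark
# (minimum/barrier) detection on the resulting profiles.

#' WHAM configuration
#'
#' @param bin_width Histogram bin width, A (default 0.05, fine enough to
#'   resolve sub-A landmark structure).
#' @param tolerance Convergence tolerance on the window free-energy
#'   offsets, kcal/mol (default 1e-7).
#' @param max_iterations Iteration cap (default 1e5).
#' @param temperature Temperature, K.
#' @return An object of class `wham_config`.
#' @export
wham_config <- function(bin_width = 0.05, tolerance = 1e-7,
                        max_iterations = 1e5, temperature = 300) {
  stopifnot(bin_width > 0, tolerance > 0, max_iterations >= 1,
            temperature > 0)
  structure(list(bin_width = bin_width, tolerance = tolerance,
                 max_iterations = as.integer(max_iterations),
                 temperature = temperature), class = "wham_config")
}

#' Umbrella window: a restraint plus its sampled coordinate series
#' @param restraint A [restraint_spec()].
#' @param series A `time_series` of reaction-coordinate values (A).
#' @return An object of class `us_window`.
#' @export
us_window <- function(restraint, series) {
  stopifnot(inherits(restraint, "restraint_spec"),
            inherits(series, "time_series"))
  if (length(series$values) == 0) stop("window series must be non-empty")
  structure(list(restraint = restraint, series = series),
            class = "us_window")
}

#' Plan umbrella windows along a coordinate range
#'
#' Evenly spaced restraint centers covering `[r_min, r_max]`. When the
#' spacing exceeds the range a single window at the midpoint is returned.
#'
#' @param r_min,r_max Coordinate range, A (`r_min < r_max`).
#' @param spacing Center-to-center distance, A (> 0).
#' @param k_default Restraint constant applied to every window,
#'   kcal/(mol*A^2); individual windows can be retuned afterwards.
#' @return List of [restraint_spec()] objects with strictly increasing
#'   centers.
#' @export
plan_windows <- function(r_min, r_max, spacing, k_default = 10) {
  if (!(r_min < r_max)) stop("degenerate range: need r_min < r_max")
  if (spacing <= 0) stop("spacing must be positive")
  centers <- if (spacing > r_max - r_min) (r_min + r_max) / 2 else
    seq(r_min, r_max, by = spacing)
  lapply(centers, function(r0) restraint_spec(k_default, r0))
}

#' Run umbrella sampling over a set of windows
#'
#' Samples each biased window independently (derived sub-seeds from
#' `cfg$seed`) and returns `us_window` objects ready for [wham_solve()].
#'
#' @param system A 1-d [toy_system()] (typically `ion_pair_continuum`).
#' @param restraints List of [restraint_spec()], e.g. from
#'   [plan_windows()].
#' @param cfg A [sampler_config()].
#' @return List of [us_window()] objects.
#' @export
run_us <- function(system, restraints, cfg) {
  seeds <- derive_seeds(cfg$seed, length(restraints))
  Map(function(rs, sd) {
    cfg_i <- cfg
    cfg_i$seed <- sd
    us_window(rs, sample_canonical(system, cfg_i, bias = rs))
  }, restraints, seeds)
}

#' Histogram overlap between adjacent umbrella windows
#'
#' Overlap coefficient (sum of bin-wise minima of the two normalized
#' histograms, in \[0, 1\]) for each adjacent pair, the stated criterion
#' for window placement: neighboring windows must overlap.
#'
#' @param windows List of [us_window()] objects, ordered by center.
#' @param bin_width Histogram bin width, A.
#' @param warn_below Pairs with overlap below this value are listed in the
#'   `warnings` attribute (default 0.05).
#' @return Data frame (window_i, window_j, overlap) with a `warnings`
#'   attribute naming the deficient pairs.
#' @export
check_overlap <- function(windows, bin_width = 0.05, warn_below = 0.05) {
  if (length(windows) < 2) stop("need at least two windows with samples")
  vals <- lapply(windows, function(w) w$series$values)
  if (any(vapply(vals, length, 1L) == 0))
    stop("empty window series")
  rng <- range(unlist(vals))
  breaks <- seq(floor(rng[1] / bin_width) * bin_width,
                rng[2] + bin_width, by = bin_width)
  hists <- lapply(vals, function(v) {
    h <- tabulate(findInterval(v, breaks, all.inside = TRUE),
                  nbins = length(breaks) - 1)
    h / sum(h)
  })
  n <- length(windows)
  ov <- vapply(seq_len(n - 1), function(i)
    sum(pmin(hists[[i]], hists[[i + 1]])), numeric(1))
  out <- data.frame(window_i = seq_len(n - 1), window_j = seq(2, n),
                    overlap = ov)
  attr(out, "warnings") <- which(ov < warn_below)
  out
}

#' Solve the WHAM equations for a PMF
#'
#' Self-consistent iteration of the standard WHAM equations over the
#' biased window histograms: unbiased bin probabilities and window offsets
#' are alternated until the largest offset change falls below the
#' tolerance. Deterministic given its inputs. Bins whose raw count falls
#' below `min_count` are reported as gaps (NA), never interpolated.
#'
#' @param windows List of [us_window()] objects.
#' @param cfg A [wham_config()].
#' @param min_count Minimum raw count for a bin to be reported (default
#'   10).
#' @return An object of class `pmf_profile`: `bin_centers` (A),
#'   `free_energy` (kcal/mol, min 0 over reported bins), `n_eff` (raw
#'   counts), `temperature`, `iterations`, `offsets`.
#' @export
wham_solve <- function(windows, cfg = wham_config(), min_count = 10) {
  stopifnot(all(vapply(windows, inherits, TRUE, "us_window")))
  kT <- R_GAS * cfg$temperature
  vals <- lapply(windows, function(w) w$series$values)
  rng <- range(unlist(vals))
  breaks <- seq(floor(rng[1] / cfg$bin_width) * cfg$bin_width,
                rng[2] + cfg$bin_width, by = cfg$bin_width)
  centers <- head(breaks, -1) + cfg$bin_width / 2
  B <- length(centers)
  W <- length(windows)
  H <- vapply(vals, function(v)
    tabulate(findInterval(v, breaks, all.inside = TRUE), nbins = B),
    numeric(B)) # B x W
  Ni <- colSums(H)
  h_tot <- rowSums(H)
  # bias energy of window j evaluated at each bin center
  C <- vapply(windows, function(w)
    0.5 * w$restraint$k_rest * (centers - w$restraint$r0)^2,
    numeric(B)) # B x W
  expC <- exp(-C / kT)
  f <- numeric(W)
  for (it in seq_len(cfg$max_iterations)) {
    denom <- as.vector(expC %*% (Ni * exp(f / kT)))
    p <- ifelse(denom > 0, h_tot / denom, 0)
    f_new <- -kT * log(as.vector(crossprod(expC, p)))
    f_new <- f_new - f_new[1]
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < cfg$tolerance) break
  }
  if (delta >= cfg$tolerance)
    stop(sprintf(paste0("WHAM failed to converge in %d iterations ",
                        "(residual %.3g kcal/mol)"),
                 cfg$max_iterations, delta))
  g <- ifelse(p > 0, -kT * log(p), NA_real_)
  g[h_tot < min_count] <- NA_real_
  g <- g - min(g, na.rm = TRUE)
  structure(list(bin_centers = centers, free_energy = g, n_eff = h_tot,
                 temperature = cfg$temperature, iterations = it,
                 offsets = f, reference = "min"),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  ok <- is.finite(x$free_energy)
  cat(sprintf(paste0("<pmf_profile> %d bins (%d reported), r in ",
                     "[%.2f, %.2f] A, max Delta G = %.2f kcal/mol\n"),
              length(x$bin_centers), sum(ok), min(x$bin_centers),
              max(x$bin_centers), max(x$free_energy[ok])))
  invisible(x)
}

#' Binding free energy from a PMF
#'
#' Default definition: the free energy of the global minimum inside the
#' bound region (r <= `bound_max_r`) minus the mean free energy over the
#' unbound plateau. A 1-d standard-length correction (reduction of the
#' thermally weighted bound-well width to 1 A) is computed and reported
#' separately in the `standard_state_correction` attribute; it is never
#' silently added.
#'
#' @param pmf A [wham_solve()] profile.
#' @param bound_max_r Outer edge of the bound region, A.
#' @param plateau_range Range `c(lo, hi)` defining the unbound plateau;
#'   default the outermost 15\% of the reported coordinate range.
#' @param flat_slope_max Plateau flatness threshold, kcal/(mol*A); a
#'   steeper fitted slope attaches a warning to the result (default 0.1).
#' @return Delta G_bind (kcal/mol) with attributes `plateau_slope`,
#'   `standard_state_correction`, and (possibly) `warning`.
#' @export
binding_dg_from_pmf <- function(pmf, bound_max_r, plateau_range = NULL,
                                flat_slope_max = 0.1) {
  ok <- is.finite(pmf$free_energy)
  r <- pmf$bin_centers[ok]
  g <- pmf$free_energy[ok]
  if (is.null(plateau_range)) {
    lo <- max(r) - 0.15 * diff(range(r))
    plateau_range <- c(lo, max(r))
  }
  pl <- r >= plateau_range[1] & r <= plateau_range[2]
  if (sum(pl) < 2) stop("plateau range is unsampled")
  bnd <- r <= bound_max_r
  if (!any(bnd)) stop("no reported bins inside the bound region")
  slope <- unname(coef(lm(g[pl] ~ r[pl]))[2])
  dg <- min(g[bnd]) - mean(g[pl])
  # thermally weighted bound-well width vs the 1 A standard length
  kT <- R_GAS * pmf$temperature
  w_eff <- sum(exp(-(g[bnd] - min(g[bnd])) / kT)) *
    (pmf$bin_centers[2] - pmf$bin_centers[1])
  attr(dg, "plateau_slope") <- slope
  attr(dg, "standard_state_correction") <- -kT * log(w_eff / 1.0)
  if (abs(slope) > flat_slope_max)
    attr(dg, "warning") <- sprintf(
      "plateau is not flat: |slope| = %.3f kcal/(mol*A)", abs(slope))
  dg
}

#' Locate minima and barriers on a PMF
#'
#' Landmarks are found on a moving-average smoothed copy (window 3 bins;
#' the stored profile itself is never smoothed): interior local minima and
#' maxima, with alternation enforced (of two adjacent minima the deeper is
#' kept, of two adjacent barriers the higher). Labels A, B, C, ... are
#' assigned in order of increasing r. Free energies are read from the
#' unsmoothed profile at the landmark bins.
#'
#' Statistically insignificant wiggles are pruned: adjacent
#' minimum/barrier pairs whose free-energy separation is below
#' `min_prominence` are removed (smallest first) until every remaining
#' pair is prominent.
#'
#' @param pmf A [wham_solve()] profile with at least 5 reported bins.
#' @param smooth_window Moving-average width in bins (odd, default 3).
#' @param min_prominence Minimum free-energy separation between adjacent
#'   landmarks, kcal/mol (default 0.1, a few times the bin-level
#'   statistical noise of a well-sampled profile).
#' @return An object of class `landmark_set`: data frame with columns
#'   `label`, `kind` ("minimum"/"barrier"), `r`, `delta_G` (possibly
#'   zero rows).
#' @export
find_landmarks <- function(pmf, smooth_window = 3, min_prominence = 0.1) {
  ok <- is.finite(pmf$free_energy)
  r <- pmf$bin_centers[ok]
  g <- pmf$free_energy[ok]
  if (length(g) < 5) stop("need at least 5 reported bins")
  k <- smooth_window
  gs <- stats::filter(g, rep(1 / k, k), sides = 2)
  gs[is.na(gs)] <- g[is.na(gs)]
  d <- diff(as.numeric(gs))
  s <- sign(d)
  s[s == 0] <- 1
  idx <- which(diff(s) != 0) + 1
  # interior landmarks only: extrema within a few bins of the profile
  # ends are edge artifacts of sparse sampling, not structure
  guard <- max(3, smooth_window)
  idx <- idx[idx > guard & idx <= length(g) - guard]
  if (length(idx) == 0)
    return(structure(data.frame(label = character(), kind = character(),
                                r = numeric(), delta_G = numeric()),
                     class = c("landmark_set", "data.frame")))
  kind <- ifelse(s[idx - 1] < 0, "minimum", "barrier")
  # enforce alternation: collapse runs of the same kind
  keep <- rep(TRUE, length(idx))
  i <- 1
  while (i < length(idx)) {
    j <- i + 1
    while (j <= length(idx) && kind[j] == kind[i]) j <- j + 1
    if (j - i > 1) {
      run <- i:(j - 1)
      best <- if (kind[i] == "minimum") run[which.min(g[idx[run]])] else
        run[which.max(g[idx[run]])]
      keep[setdiff(run, best)] <- FALSE
    }
    i <- j
  }
  idx <- idx[keep]
  kind <- kind[keep]
  # prune insignificant wiggles: drop the least prominent adjacent pair
  # until all neighbors are separated by at least min_prominence
  while (length(idx) > 1) {
    sep <- abs(diff(g[idx]))
    if (min(sep) >= min_prominence) break
    i <- which.min(sep)
    idx <- idx[-c(i, i + 1)]
    kind <- kind[-c(i, i + 1)]
  }
  # interior landmarks only: a surviving lone extremum at a profile edge
  # with nothing to alternate against is still reported
  out <- data.frame(label = landmark_labels(length(idx)), kind = kind,
                    r = r[idx], delta_G = g[idx])
  structure(out, class = c("landmark_set", "data.frame"))
}

landmark_labels <- function(n) {
  if (n == 0) return(character(0))
  if (n <= 26) return(LETTERS[seq_len(n)])
  c(LETTERS, paste0(rep(LETTERS, each = 26), LETTERS))[seq_len(n)]
}
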