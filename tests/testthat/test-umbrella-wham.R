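make_pmf <- function(r, g, n_eff = rep(1000, length(r)),
                     temperature = 300) {
  structure(list(bin_centers = r, free_energy = g, n_eff = n_eff,
                 temperature = temperature, iterations = 0L,
                 offsets = NULL, reference = "min"),
            class = "pmf_profile")
}

test_that("window planning covers the range with even spacing", {
  w <- plan_windows(2, 11, 0.5)
  expect_length(w, 19)
  centers <- vapply(w, `[[`, numeric(1), "r0")
  expect_true(all(diff(centers) > 0))
  expect_equal(centers[1], 2)
  expect_equal(centers[19], 11)
  # spacing wider than the range: one window at the midpoint
  w1 <- plan_windows(3, 5, 10)
  expect_length(w1, 1)
  expect_equal(w1[[1]]$r0, 4)
  expect_error(plan_windows(5, 5, 0.5), "degenerate")
  expect_error(plan_windows(2, 11, -1), "spacing")
})

test_that("histogram overlap matches the Gaussian closed form", {
  # biased sampling on a flat potential gives Gaussians of sd
  # sqrt(kT/k); overlap of equal-width Gaussians d apart is 2*Phi(-d/2sd)
  sys <- toy_system("flat", domain = c(0, 12))
  k <- 10
  sdv <- sqrt(R_GAS * 300 / k)
  mk <- function(r0, seed)
    us_window(restraint_spec(k, r0),
              sample_canonical(sys, quick_cfg(6e4, seed, step_size = 0.4),
                               bias = restraint_spec(k, r0)))
  wA <- mk(5, 1)
  wB <- mk(5 + sdv, 2)
  ov <- check_overlap(list(wA, wB))
  expect_equal(ov$overlap, 2 * stats::pnorm(-0.5), tolerance = 0.04)
  # identical windows (same seed): overlap exactly 1
  ov1 <- check_overlap(list(wA, wA))
  expect_equal(ov1$overlap, 1)
  # far-separated stiff windows: overlap ~ 0 and flagged
  wC <- mk(10, 3)
  ov0 <- check_overlap(list(wA, wC))
  expect_lt(ov0$overlap, 0.01)
  expect_equal(attr(ov0, "warnings"), 1L)
})

test_that("WHAM reduces to the unbiased histogram for a single window", {
  sys <- toy_system("doublewell1d", h = 1.2)
  ts <- sample_canonical(sys, quick_cfg(2e5, seed = 6))
  # a vanishing bias makes the window effectively unbiased
  w <- us_window(restraint_spec(1e-9, 4), ts)
  pmf <- wham_solve(list(w), wham_config(bin_width = 0.1))
  kT <- R_GAS * 300
  h <- pmf$n_eff
  ref <- -kT * log(h / sum(h))
  ref <- ref - min(ref[is.finite(pmf$free_energy)])
  ok <- is.finite(pmf$free_energy)
  expect_lt(max(abs(pmf$free_energy[ok] - ref[ok])), 1e-8)
})

test_that("WHAM recovers the analytic double-well profile", {
  sys <- toy_system("doublewell1d")
  wins <- run_us(sys, plan_windows(1.5, 6.5, 0.4, k_default = 15),
                 quick_cfg(3e4, seed = 11))
  pmf <- wham_solve(wins)
  ok <- is.finite(pmf$free_energy) & pmf$n_eff > 300
  u <- system_energy(sys, pmf$bin_centers[ok])
  dev <- (pmf$free_energy[ok] - min(pmf$free_energy[ok])) - (u - min(u))
  expect_lt(sqrt(mean(dev^2)), 0.15)
})

test_that("splitting a window into identical halves leaves the PMF fixed", {
  sys <- toy_system("doublewell1d")
  wins <- run_us(sys, plan_windows(2, 6, 0.5, k_default = 12),
                 quick_cfg(2e4, seed = 3))
  pmf_a <- wham_solve(wins)
  v <- wins[[4]]$series$values
  half <- length(v) %/% 2
  w1 <- us_window(wins[[4]]$restraint,
                  lj1264:::new_time_series(v[seq_len(half)], NA, list()))
  w2 <- us_window(wins[[4]]$restraint,
                  lj1264:::new_time_series(v[(half + 1):length(v)], NA,
                                           list()))
  pmf_b <- wham_solve(c(wins[-4], list(w1, w2)))
  expect_equal(pmf_b$free_energy, pmf_a$free_energy, tolerance = 1e-8)
})

test_that("WHAM is invariant under a rigid shift of the coordinate frame", {
  sys <- toy_system("doublewell1d")
  wins <- run_us(sys, plan_windows(2, 6, 0.5, k_default = 12),
                 quick_cfg(2e4, seed = 8))
  shift <- 0.5 # integer multiple of the bin width keeps bins aligned
  wins_s <- lapply(wins, function(w) {
    ts <- w$series
    ts$values <- ts$values + shift
    us_window(restraint_spec(w$restraint$k_rest, w$restraint$r0 + shift),
              ts)
  })
  pmf_a <- wham_solve(wins)
  pmf_b <- wham_solve(wins_s)
  expect_equal(pmf_b$bin_centers, pmf_a$bin_centers + shift,
               tolerance = 1e-9)
  expect_equal(pmf_b$free_energy, pmf_a$free_energy, tolerance = 1e-7)
})

test_that("binding free energy follows the well-minus-plateau definition", {
  # identically flat profile: zero binding free energy
  r <- seq(2, 12, by = 0.05)
  expect_equal(as.numeric(
    binding_dg_from_pmf(make_pmf(r, rep(0, length(r))), 5)), 0)
  # square well of depth 3: Delta G = -3, and deepening by delta lowers
  # the result by exactly delta
  g <- ifelse(r < 4, 0, 3)
  g <- g - min(g)
  pmf <- make_pmf(r, g)
  expect_equal(as.numeric(binding_dg_from_pmf(pmf, 5)), -3)
  g2 <- ifelse(r < 4, -0.75, 3)
  g2 <- g2 - min(g2)
  expect_equal(as.numeric(binding_dg_from_pmf(make_pmf(r, g2), 5)),
               -3.75)
  # invariance to the additive reference
  g3 <- g + 7 # as if referenced elsewhere
  expect_equal(as.numeric(binding_dg_from_pmf(make_pmf(r, g3), 5)),
               as.numeric(binding_dg_from_pmf(pmf, 5)))
  # a sloped plateau attaches a warning
  gw <- 0.5 * (r - 2)
  expect_match(attr(binding_dg_from_pmf(make_pmf(r, gw), 5), "warning"),
               "not flat")
  # unsampled plateau errors
  pmf_gap <- make_pmf(r, ifelse(r > 10, NA_real_, g))
  expect_error(binding_dg_from_pmf(pmf_gap, 5, plateau_range = c(10.5, 12)),
               "unsampled")
})

test_that("landmark detection finds the double-well extrema", {
  r <- seq(2, 6, by = 0.05)
  sys <- toy_system("doublewell1d")
  # monotone profile: no interior landmarks
  mono <- find_landmarks(make_pmf(r, (r - 2) * 1.5))
  expect_equal(nrow(mono), 0)
  # analytic double well: two minima and one barrier, alternating
  u <- system_energy(sys, r)
  lm <- find_landmarks(make_pmf(r, u - min(u)))
  expect_equal(sum(lm$kind == "minimum"), 2)
  expect_equal(sum(lm$kind == "barrier"), 1)
  expect_equal(lm$kind, c("minimum", "barrier", "minimum"))
  expect_equal(lm$label, c("A", "B", "C"))
  expect_lt(abs(lm$r[1] - 3), 0.051)
  expect_lt(abs(lm$r[2] - 4), 0.051)
  expect_lt(abs(lm$r[3] - 5), 0.051)
  # landmark heights are read off the profile itself
  for (i in seq_len(nrow(lm))) {
    bin <- which.min(abs(r - lm$r[i]))
    expect_equal(lm$delta_G[i], (u - min(u))[bin])
  }
})

test_that("binding free energy responds monotonically to C4", {
  sys <- toy_system("ion_pair_continuum")
  obj <- binding_objective(sys, quick_cfg(2.5e4, seed = 1))
  dgs <- vapply(c(-150, 0, 150), function(c4) obj(c4, 17), numeric(1))
  expect_true(all(diff(dgs) < 0))
})
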