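test_that("12-6-4 pair energy reduces, scales linearly, and has the closed-form minimum", {
  p0 <- pair_params(C12 = 6e5, C6 = 600, C4 = 0)
  r <- seq(2, 10, by = 0.25)
  expect_equal(lj124_pair_energy(r, p0), p0$C12 / r^12 - p0$C6 / r^6)

  # closed-form minimum of the 12-6 form, cross-checked by a dense scan
  rmin <- (2 * p0$C12 / p0$C6)^(1 / 6)
  umin <- -p0$C6^2 / (4 * p0$C12)
  expect_equal(lj124_pair_energy(rmin, p0), umin, tolerance = 1e-12)
  grid <- seq(rmin - 0.5, rmin + 0.5, by = 1e-4)
  expect_equal(min(lj124_pair_energy(grid, p0)), umin, tolerance = 1e-6)
  expect_lt(abs(grid[which.min(lj124_pair_energy(grid, p0))] - rmin), 1e-3)

  # adding C4 = c lowers the energy by exactly c/r^4; linearity in each
  # coefficient
  c4 <- 104
  pc <- pair_params(C12 = 6e5, C6 = 600, C4 = c4)
  expect_equal(lj124_pair_energy(r, pc), lj124_pair_energy(r, p0) - c4 / r^4)
  for (fld in c("C12", "C6", "C4")) {
    p2 <- pc
    p2[[fld]] <- 2 * p2[[fld]]
    pz <- pc
    pz[[fld]] <- 0
    expect_equal(lj124_pair_energy(3, p2) - lj124_pair_energy(3, pc),
                 lj124_pair_energy(3, pc) - lj124_pair_energy(3, pz))
  }
  expect_error(lj124_pair_energy(0, p0), "positive")
  expect_error(lj124_pair_energy(-1, p0), "positive")
})

test_that("Coulomb energy has 1/r scaling and the exact constant", {
  expect_equal(coulomb_pair_energy(seq(1, 5), 0, 1), rep(0, 5))
  e1 <- coulomb_pair_energy(2, 1, 1)
  expect_equal(coulomb_pair_energy(4, 1, 1), e1 / 2)
  # direct evaluation with k_C = 332.0637
  expect_equal(coulomb_pair_energy(3.320637, 2, -1), -200.0,
               tolerance = 1e-10)
  expect_equal(coulomb_pair_energy(3, 1, -1, dielectric = 78.5),
               coulomb_pair_energy(3, 1, -1) / 78.5)
  expect_error(coulomb_pair_energy(0, 1, 1), "positive")
  expect_error(coulomb_pair_energy(1, 1, 1, dielectric = 0.5), ">= 1")
})

test_that("C4 from polarizability is linear in alpha0 and quadratic in Q", {
  expect_equal(c4_from_polarizability(0, 2), 0)
  expect_equal(c4_from_polarizability(2.4, 1),
               2 * c4_from_polarizability(1.2, 1))
  expect_equal(c4_from_polarizability(1.5, 2) /
                 c4_from_polarizability(1.5, 1), 4)
})

test_that("soft-core vdW honors endpoint identities and is regular at r = 0", {
  p <- pair_params(C12 = 6e5, C6 = 600, C4 = 50)
  r <- seq(0.5, 8, by = 0.1)
  plain <- p$C12 / r^12 - p$C6 / r^6
  expect_equal(softcore_vdw(r, softcore_spec(1), p), plain,
               tolerance = 1e-12)
  expect_equal(softcore_vdw(r, softcore_spec(0), p), rep(0, length(r)))
  expect_true(is.finite(softcore_vdw(0, softcore_spec(0.5), p)))
  # continuity in lambda on [0, 1]
  lams <- seq(0, 1, by = 0.01)
  u <- vapply(lams, function(l) softcore_vdw(3, softcore_spec(l), p),
              numeric(1))
  expect_lt(max(abs(diff(u))), 0.05)
  expect_error(softcore_spec(1.2), "lambda")
  expect_error(softcore_spec(0.5, alpha_sc = 0), "alpha_sc")
})

test_that("total energy composes pair terms and flags missing parameters", {
  tab <- single_type_table(Q = 0.5)
  expect_equal(total_energy(configuration(matrix(0, 1, 3), "X"), tab), 0)

  cfg2 <- configuration(rbind(c(0, 0, 0), c(3, 0, 0)), c("X", "X"))
  p <- pair_params(6e5, 600, 0)
  expect_equal(total_energy(cfg2, tab),
               lj124_pair_energy(3, p) + coulomb_pair_energy(3, 0.5, 0.5))

  # equilateral triangle: brute-force sum equals 3x the pair value
  a <- 3.4
  tri <- configuration(rbind(c(0, 0, 0), c(a, 0, 0),
                             c(a / 2, a * sqrt(3) / 2, 0)), rep("X", 3))
  expect_equal(total_energy(tri, tab),
               3 * (lj124_pair_energy(a, p) +
                      coulomb_pair_energy(a, 0.5, 0.5)),
               tolerance = 1e-12)

  cfg_bad <- configuration(rbind(c(0, 0, 0), c(3, 0, 0)), c("X", "Y"))
  expect_error(total_energy(cfg_bad, tab), "\\(X, Y\\)")
})

test_that("energy is invariant under rigid translations and rotations", {
  tab <- single_type_table(C4 = 80, Q = 0.3)
  for (seed in 1:3) {
    cfg <- random_config(5, seed)
    e0 <- total_energy(cfg, tab, cutoff = 50)
    set.seed(seed + 100)
    shift <- runif(3, -5, 5)
    th <- runif(1, 0, 2 * pi)
    rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0),
                 c(0, 0, 1))
    cfg2 <- cfg
    cfg2$coordinates <- sweep(cfg$coordinates %*% t(rot), 2, -shift)
    expect_equal(total_energy(cfg2, tab, cutoff = 50), e0,
                 tolerance = 1e-10)
  }
})

test_that("analytic forces match the numerical gradient of the energy", {
  tab <- single_type_table(C4 = 60, Q = 0.4)
  h <- 1e-5
  for (seed in 1:2) {
    cfg <- random_config(4, seed, spread = 5)
    f <- total_forces(cfg, tab, cutoff = 50)
    for (i in seq_len(4)) {
      for (d in 1:3) {
        cp <- cfg
        cm <- cfg
        cp$coordinates[i, d] <- cp$coordinates[i, d] + h
        cm$coordinates[i, d] <- cm$coordinates[i, d] - h
        fnum <- -(total_energy(cp, tab, cutoff = 50) -
                    total_energy(cm, tab, cutoff = 50)) / (2 * h)
        expect_equal(f[i, d], fnum, tolerance = 1e-5)
      }
    }
  }
})

test_that("minimum image convention folds periodic pair distances", {
  tab <- single_type_table(Q = 0)
  cfg <- configuration(rbind(c(0.5, 0, 0), c(9.5, 0, 0)), c("X", "X"),
                       box = 10)
  p <- pair_params(6e5, 600, 0)
  expect_equal(total_energy(cfg, tab, cutoff = 4),
               lj124_pair_energy(1, p))
})
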