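# Deterministic fixture generation: everything the other modules need for
# offline testing is built by code (synthetic stand-ins for deposited
# structure files and for sampled window data).

#' Generate a named fixture on disk
#'
#' Kinds:
#' \describe{
#'   \item{mol2_phosphate}{A phosphate-like 5-site molecule (central P
#'     plus 4 tetrahedral oxygens) written as mol2; `charge` (-1, -2 or
#'     -3) sets the exact total charge, split as P +1.4 and four equal
#'     oxygens. Synthetic stand-in for deposited structure files.}
#'   \item{doublewell_windows}{Umbrella windows sampled on the
#'     double-well toy (spacing 0.5 A over \[2, 6\]) written as a window
#'     manifest + per-window TSVs.}
#'   \item{ion_pair_windows}{Umbrella windows on the ion-pair continuum
#'     toy (spacing 0.5 A over \[2, 11\], 19 windows).}
#' }
#' Identical spec (kind, parameters, seed) produces byte-identical files.
#'
#' @param kind Fixture kind.
#' @param dir Output directory (created if absent).
#' @param seed Integer seed for sampled fixtures.
#' @param charge Total charge for `mol2_phosphate` (-1, -2, -3).
#' @param n_steps Chain length per window for sampled fixtures.
#' @return Path of the primary generated file, invisibly.
#' @export
make_fixture <- function(kind = c("mol2_phosphate", "doublewell_windows",
                                  "ion_pair_windows"),
                         dir, seed = 1L, charge = -1, n_steps = 20000) {
  kind <- match.arg(kind)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  switch(kind,
    mol2_phosphate = {
      stopifnot(charge %in% c(-1, -2, -3))
      # tetrahedral P-O geometry, bond length 1.54 A
      d <- 1.54 / sqrt(3)
      xyz <- rbind(c(0, 0, 0), c(d, d, d), c(d, -d, -d), c(-d, d, -d),
                   c(-d, -d, d))
      q_o <- (charge - 1.4) / 4
      f <- file.path(dir, sprintf("phosphate_q%d_synthetic.mol2", charge))
      write_mol2(f, sprintf("phosphate_q%d_synthetic", charge),
                 c("P1", "O1", "O2", "O3", "O4"), xyz,
                 c("P.3", "O.3", "O.3", "O.3", "O.3"),
                 c(1.4, rep(q_o, 4)))
      invisible(f)
    },
    doublewell_windows = {
      sys <- toy_system("doublewell1d")
      cfg <- sampler_config(n_steps = n_steps, seed = seed, thin = 1)
      wins <- run_us(sys, plan_windows(2, 6, 0.5, k_default = 10), cfg)
      invisible(write_window_set(wins, dir))
    },
    ion_pair_windows = {
      sys <- toy_system("ion_pair_continuum", C4 = 50)
      cfg <- sampler_config(n_steps = n_steps, seed = seed, thin = 1)
      wins <- run_us(sys, plan_windows(2, 11, 0.5, k_default = 10), cfg)
      invisible(write_window_set(wins, dir))
    }
  )
}

#' Read a PMF profile written by [write_pmf_tsv()]
#' @param path TSV path.
#' @param temperature Temperature to attach, K.
#' @return A `pmf_profile`.
#' @export
read_pmf_tsv <- function(path, temperature = 300) {
  dat <- read.csv(path, sep = "\t", comment.char = "#", header = FALSE,
                  col.names = c("bin_center", "delta_G", "n_eff"))
  structure(list(bin_centers = dat$bin_center, free_energy = dat$delta_G,
                 n_eff = dat$n_eff, temperature = temperature,
                 iterations = NA_integer_, offsets = NULL,
                 reference = "min"),
            class = "pmf_profile")
}

#' Packaged experimental target table
#'
#' The experimental free-energy targets shipped with the package
#' (hydration free energies of the three phosphate protonation states and
#' metal-phosphate binding free energies derived from association
#' constants at 298 K), as a data frame with columns species, metal,
#' observable, target_dG, tolerance.
#'
#' @return Data frame of fitting targets.
#' @export
packaged_targets <- function() {
  read.csv(system.file("extdata", "experimental_targets.csv",
                       package = "lj1264"))
}
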