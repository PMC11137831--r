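# Built-in toy systems: desk-scale stand-ins for explicit-solvent boxes.
# Each system exposes an equilibrium distribution that the Metropolis
# sampler targets; free energies and PMFs depend only on that distribution.

KIND_CODES <- c(flat = 0L, harmonic1d = 1L, doublewell1d = 2L,
                ion_pair_continuum = 3L)

#' Construct a toy system
#'
#' Four families are available:
#' \describe{
#'   \item{harmonic1d}{U(x) = k (x - x0)^2 / 2. Parameters `k`
#'     (kcal/(mol*A^2), default 1) and `x0` (default 0).}
#'   \item{doublewell1d}{Quartic double well
#'     U(x) = h ((x - m)^2 - d^2)^2 / d^4 with wells at m - d and m + d and
#'     barrier height h at x = m. Defaults h = 3 kcal/mol, m = 4 A,
#'     d = 1 A.}
#'   \item{flat}{U = 0 on `[domain[1], domain[2]]` (hard walls).}
#'   \item{ion_pair_continuum}{A divalent cation and a charged ligand site
#'     on a 1-d separation coordinate in a dielectric continuum:
#'     U(r) = C12/r^12 - C6/r^6 - C4/r^4 + k_C q_ion q_site/(dielectric r).
#'     Defaults C12 = 6e5, C6 = 600, C4 = 0, q_ion = +2, q_site = -1,
#'     dielectric = 78.5 (aqueous continuum).}
#'   \item{micro_solvation_box}{A charged solute bead plus `n_solvent`
#'     neutral-pair solvent beads (alternating +/- partial charges, net
#'     zero) in a periodic cubic box, <= 32 particles. Solvent-solvent
#'     pairs use a full 12-6 + Coulomb potential; solute-solvent pairs are
#'     the alchemical 12-6-4 + Coulomb interaction whose C4 term (`C4_us`)
#'     is the tunable quantity. NVT by construction.}
#' }
#'
#' @param kind One of "harmonic1d", "doublewell1d", "flat",
#'   "ion_pair_continuum", "micro_solvation_box".
#' @param ... Kind-specific parameter overrides (see Details).
#' @param k Spring constant of `harmonic1d`, kcal/(mol*A^2); a separate
#'   formal so it is never partially matched against `kind`.
#' @return An object of class `toy_system`.
#' @export
toy_system <- function(kind = c("harmonic1d", "doublewell1d", "flat",
                                "ion_pair_continuum", "micro_solvation_box"),
                       ..., k = NULL) {
  kind <- match.arg(kind)
  over <- list(...)
  if (!is.null(k)) over$k <- k
  pars <- switch(kind,
    harmonic1d = list(k = 1, x0 = 0, domain = c(-25, 25), step = 1.6,
                      init = NULL),
    doublewell1d = list(h = 3, m = 4, d = 1, domain = c(1, 7), step = 0.45,
                        init = NULL),
    flat = list(domain = c(0, 10), step = 6, init = NULL),
    ion_pair_continuum = list(C12 = 6e5, C6 = 600, C4 = 0, q_ion = 2,
                              q_site = -1, dielectric = 78.5,
                              domain = c(2, 12), step = 0.9, init = 3.2),
    micro_solvation_box = list(n_solvent = 14, box = 12, cutoff = 6,
                               eps_ss = 0.1, sigma_ss = 3.0,
                               q_solvent = 0.05, q_solute = 0.5,
                               C12_us = 425000, C6_us = 583, C4_us = 0,
                               alpha_sc = 0.5, step = 0.6)
  )
  unknown <- setdiff(names(over), names(pars))
  if (length(unknown))
    stop("unknown parameters for ", kind, ": ",
         paste(unknown, collapse = ", "))
  pars[names(over)] <- over
  if (kind == "micro_solvation_box" && pars$n_solvent + 1 > 32)
    stop("micro_solvation_box is limited to 32 particles")
  structure(list(kind = kind, pars = pars), class = "toy_system")
}

#' @export
print.toy_system <- function(x, ...) {
  cat("<toy_system:", x$kind, ">\n")
  utils::str(x$pars, give.head = FALSE)
  invisible(x)
}

# scalar potential of a 1-d toy (used by analytic oracles and WHAM checks)
#' Evaluate the potential of a 1-d toy system
#' @param system A 1-d [toy_system()].
#' @param x Coordinate values, A.
#' @return Energy, kcal/mol.
#' @export
system_energy <- function(system, x) {
  p <- system$pars
  switch(system$kind,
    flat = rep(0, length(x)),
    harmonic1d = 0.5 * p$k * (x - p$x0)^2,
    doublewell1d = p$h * ((x - p$m)^2 - p$d^2)^2 / p$d^4,
    ion_pair_continuum =
      p$C12 / x^12 - p$C6 / x^6 - p$C4 / x^4 +
        K_COULOMB * p$q_ion * p$q_site / (p$dielectric * x),
    stop("system_energy is defined for 1-d systems only")
  )
}

is_1d_system <- function(system) system$kind %in% names(KIND_CODES)

pars_vector_1d <- function(system) {
  p <- system$pars
  switch(system$kind,
    flat = numeric(0),
    harmonic1d = c(p$k, p$x0),
    doublewell1d = c(p$h, p$m, p$d),
    ion_pair_continuum = c(p$C12, p$C6, p$C4, p$q_ion * p$q_site,
                           p$dielectric)
  )
}

init_coord_1d <- function(system) {
  p <- system$pars
  if (!is.null(p$init)) return(p$init)
  switch(system$kind,
    flat = mean(p$domain),
    harmonic1d = p$x0,
    doublewell1d = p$m - p$d,
    ion_pair_continuum = 3.2
  )
}

# deterministic simple-cubic starting lattice for the micro box
box_lattice <- function(n, L) {
  m <- ceiling(n^(1 / 3))
  g <- (seq_len(m) - 0.5) * L / m
  xyz <- as.matrix(expand.grid(x = g, y = g, z = g))
  xyz[seq_len(n), , drop = FALSE]
}

box_charges <- function(system) {
  p <- system$pars
  qs <- rep(c(p$q_solvent, -p$q_solvent), length.out = p$n_solvent)
  if (p$n_solvent %% 2 == 1) qs[p$n_solvent] <- 0 # keep the bath neutral
  c(p$q_solute, qs)
}

box_c12c6_ss <- function(system) {
  p <- system$pars
  c(C12 = 4 * p$eps_ss * p$sigma_ss^12, C6 = 4 * p$eps_ss * p$sigma_ss^6)
}
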