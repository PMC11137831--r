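# 12-6-4 pairwise energetics: the plain Lennard-Jones 12-6 form augmented
# with a C4/r^4 ion-induced-dipole term, point-charge Coulomb interactions,
# and the lambda-dependent soft-core form used for alchemical decoupling.

#' Define an atom type
#'
#' An atom type carries the per-atom quantities entering the 12-6-4 model:
#' partial charge, self 12-6 coefficients, and the polarizability used to
#' derive C4 cross-terms.
#'
#' @param name Atom-type label.
#' @param Q Partial charge, units of elementary charge e.
#' @param C12 Repulsive coefficient, kcal*A^12/mol (>= 0).
#' @param C6 Dispersion coefficient, kcal*A^6/mol (>= 0).
#' @param alpha0 Polarizability, A^3 (a tuned quantity; any sign allowed).
#' @return An object of class `atom_type`.
#' @export
atom_type <- function(name, Q = 0, C12 = 0, C6 = 0, alpha0 = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  if (C12 < 0 || C6 < 0) stop("C12 and C6 must be non-negative")
  structure(list(name = name, Q = Q, C12 = C12, C6 = C6, alpha0 = alpha0),
            class = "atom_type")
}

#' Define pair interaction coefficients
#'
#' Cross-term coefficients for one atom pair. C4 is signed: positive C4 is
#' attractive (the energy contribution is -C4/r^4), negative C4 repulsive.
#' No combining rule is applied to C4; it is fitted per pair.
#'
#' @param C12,C6 12-6 coefficients, kcal*A^12/mol and kcal*A^6/mol (>= 0).
#' @param C4 r^-4 cross-term, kcal*A^4/mol (any sign).
#' @return An object of class `pair_params`.
#' @export
pair_params <- function(C12 = 0, C6 = 0, C4 = 0) {
  if (C12 < 0 || C6 < 0) stop("C12 and C6 must be non-negative")
  structure(list(C12 = C12, C6 = C6, C4 = C4), class = "pair_params")
}

#' 12-6-4 pair energy
#'
#' U(r) = C12/r^12 - C6/r^6 - C4/r^4. The r^-4 term models the attraction of
#' an ion to the dipole it induces in its partner; it enters with a minus
#' sign so that a positive C4 deepens the well.
#'
#' @param r Distance, A (> 0); vectorized.
#' @param p A [pair_params()] object.
#' @return Energy, kcal/mol.
#' @export
lj124_pair_energy <- function(r, p) {
  if (any(r <= 0)) stop("pair distance must be positive")
  p$C12 / r^12 - p$C6 / r^6 - p$C4 / r^4
}

#' Radial derivative of the 12-6-4 pair energy (dU/dr), kcal/(mol*A)
#' @inheritParams lj124_pair_energy
#' @export
lj124_pair_dudr <- function(r, p) {
  if (any(r <= 0)) stop("pair distance must be positive")
  -12 * p$C12 / r^13 + 6 * p$C6 / r^7 + 4 * p$C4 / r^5
}

#' Coulomb pair energy
#'
#' Point-charge interaction k_C * Qi * Qj / (dielectric * r) with
#' k_C = 332.0637 kcal*A/(mol*e^2).
#'
#' @param r Distance, A (> 0); vectorized.
#' @param Qi,Qj Partial charges, e.
#' @param dielectric Relative dielectric constant (>= 1); 1 = vacuum.
#' @return Energy, kcal/mol.
#' @export
coulomb_pair_energy <- function(r, Qi, Qj, dielectric = 1) {
  if (any(r <= 0)) stop("pair distance must be positive")
  if (dielectric < 1) stop("dielectric must be >= 1")
  K_COULOMB * Qi * Qj / (dielectric * r)
}

#' C4 cross-term from a partner polarizability
#'
#' Ion-induced-dipole coefficient: the energy of a charge Q polarizing a
#' neutral partner of polarizability alpha0 is -k_C Q^2 alpha0 / (2 r^4),
#' giving C4 = k_C * Q^2 * alpha0 / 2 in kcal*A^4/mol. This is the model
#' convention adopted here; in parametrization work C4 itself remains the
#' primary fitted quantity and this relation is used to seed brackets.
#'
#' @param alpha0 Partner polarizability, A^3.
#' @param Q_partner Charge of the polarizing ion, e.
#' @return C4, kcal*A^4/mol.
#' @export
c4_from_polarizability <- function(alpha0, Q_partner) {
  K_COULOMB * Q_partner^2 * alpha0 / 2
}

#' Soft-core specification for alchemical decoupling
#'
#' @param lambda Coupling parameter in `[0, 1]`.
#' @param alpha_sc Dimensionless softness (default 0.5).
#' @param sigma Zero-crossing distance of the unmodified LJ potential, A.
#'   If `NULL`, derived from the pair coefficients as (C12/C6)^(1/6).
#' @return An object of class `softcore_spec`.
#' @export
softcore_spec <- function(lambda, alpha_sc = 0.5, sigma = NULL) {
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  if (alpha_sc <= 0) stop("alpha_sc must be positive")
  if (!is.null(sigma) && sigma <= 0) stop("sigma must be positive")
  structure(list(lambda = lambda, alpha_sc = alpha_sc, sigma = sigma),
            class = "softcore_spec")
}

#' Soft-core van der Waals energy
#'
#' Lambda-coupled soft-core form of the 12-6 part:
#' V(r; lambda) = 4 eps lambda \[ A^-2 - A^-1 \],
#' A = alpha_sc (1 - lambda) + (r/sigma)^6,
#' with sigma the zero crossing of the unmodified potential and
#' eps = C6^2/(4 C12) its well depth. At lambda = 1 this is exactly the
#' plain 12-6 energy; at lambda = 0 it vanishes; for lambda < 1 it is
#' finite at r = 0, removing the end-point catastrophe. The soft core is
#' applied to the 12-6 part only; the C4 term is handled by the alchemical
#' path, not here.
#'
#' @param r Distance, A (>= 0); vectorized.
#' @param sc A [softcore_spec()].
#' @param p A [pair_params()] with C12 > 0 and C6 > 0.
#' @return Energy, kcal/mol.
#' @export
softcore_vdw <- function(r, sc, p) {
  stopifnot(inherits(sc, "softcore_spec"))
  if (any(r < 0)) stop("distance must be non-negative")
  if (sc$lambda == 0) return(rep(0, length(r)))
  if (p$C12 <= 0 || p$C6 <= 0)
    stop("soft-core form needs C12 > 0 and C6 > 0 to define sigma and eps")
  sigma <- if (is.null(sc$sigma)) (p$C12 / p$C6)^(1 / 6) else sc$sigma
  eps <- p$C6^2 / (4 * p$C12)
  A <- sc$alpha_sc * (1 - sc$lambda) + (r / sigma)^6
  4 * eps * sc$lambda * (1 / A^2 - 1 / A)
}

#' Assemble a particle configuration
#'
#' @param coordinates Numeric matrix, one row per particle, columns x/y/z
#'   (A). A single column is treated as a 1-d arrangement on the x axis.
#' @param types Character vector of atom-type labels, one per particle.
#' @param box Optional cubic box edge length, A; when present the minimum
#'   image convention applies to all pair distances.
#' @return An object of class `configuration`.
#' @export
configuration <- function(coordinates, types, box = NULL) {
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) == 1) coordinates <- cbind(coordinates, 0, 0)
  stopifnot(ncol(coordinates) == 3, nrow(coordinates) == length(types))
  if (!is.null(box)) stopifnot(box > 0)
  structure(list(coordinates = coordinates, types = as.character(types),
                 box = box), class = "configuration")
}

#' Build a pair-parameter table
#'
#' Pair coefficients are stored explicitly per (unordered) type pair; no
#' combining rule is applied. Use [read_pair_overrides()] to load the CSV
#' form.
#'
#' @param df Data frame with columns type_i, type_j, C12, C6, C4.
#' @param charges Named numeric vector of per-type partial charges (e).
#' @return An object of class `pair_table`.
#' @export
pair_table <- function(df, charges = NULL) {
  need <- c("type_i", "type_j", "C12", "C6", "C4")
  if (!all(need %in% names(df)))
    stop("pair table needs columns: ", paste(need, collapse = ", "))
  key <- ifelse(df$type_i <= df$type_j,
                paste(df$type_i, df$type_j, sep = "|"),
                paste(df$type_j, df$type_i, sep = "|"))
  if (anyDuplicated(key)) stop("duplicate pair entries in pair table")
  structure(list(df = df, key = key, charges = charges), class = "pair_table")
}

pair_lookup <- function(tab, ti, tj) {
  k <- if (ti <= tj) paste(ti, tj, sep = "|") else paste(tj, ti, sep = "|")
  i <- match(k, tab$key)
  if (is.na(i))
    stop(sprintf("no pair parameters for pair (%s, %s)", ti, tj))
  pair_params(tab$df$C12[i], tab$df$C6[i], tab$df$C4[i])
}

pair_dist <- function(xi, xj, box) {
  d <- xi - xj
  if (!is.null(box)) d <- d - box * round(d / box)
  sqrt(sum(d * d))
}

#' Total nonbonded energy of a configuration
#'
#' Sum of 12-6-4 plus Coulomb energies over unique pairs within the cutoff,
#' with plain truncation (no switching, no long-range correction) and the
#' minimum image convention when the configuration is periodic.
#'
#' @param cfg A [configuration()].
#' @param params A [pair_table()]; its `charges` entry supplies per-type
#'   partial charges (defaults to zero for absent types).
#' @param cutoff Nonbonded cutoff, A (default 12).
#' @param dielectric Relative dielectric constant (default 1).
#' @return Total energy, kcal/mol.
#' @export
total_energy <- function(cfg, params, cutoff = 12, dielectric = 1) {
  stopifnot(inherits(cfg, "configuration"), inherits(params, "pair_table"))
  n <- nrow(cfg$coordinates)
  if (n < 2) return(0)
  qv <- unname(vapply(cfg$types, function(t) {
    if (!is.null(params$charges) && t %in% names(params$charges))
      params$charges[[t]] else 0
  }, numeric(1)))
  e <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      r <- pair_dist(cfg$coordinates[i, ], cfg$coordinates[j, ], cfg$box)
      if (r > cutoff) next
      p <- pair_lookup(params, cfg$types[i], cfg$types[j])
      e <- e + lj124_pair_energy(r, p) +
        coulomb_pair_energy(r, qv[i], qv[j], dielectric)
    }
  }
  e
}

#' Analytic forces for a configuration
#'
#' Negative gradient of [total_energy()] with respect to the coordinates,
#' from the analytic pair-force expressions. Pairs beyond the cutoff
#' contribute zero (consistent with plain truncation).
#'
#' @inheritParams total_energy
#' @return Numeric matrix, one row per particle (kcal/(mol*A)).
#' @export
total_forces <- function(cfg, params, cutoff = 12, dielectric = 1) {
  stopifnot(inherits(cfg, "configuration"), inherits(params, "pair_table"))
  n <- nrow(cfg$coordinates)
  f <- matrix(0, n, 3)
  if (n < 2) return(f)
  qv <- unname(vapply(cfg$types, function(t) {
    if (!is.null(params$charges) && t %in% names(params$charges))
      params$charges[[t]] else 0
  }, numeric(1)))
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      d <- cfg$coordinates[i, ] - cfg$coordinates[j, ]
      if (!is.null(cfg$box)) d <- d - cfg$box * round(d / cfg$box)
      r <- sqrt(sum(d * d))
      if (r > cutoff) next
      p <- pair_lookup(params, cfg$types[i], cfg$types[j])
      dudr <- lj124_pair_dudr(r, p) -
        K_COULOMB * qv[i] * qv[j] / (dielectric * r^2)
      fij <- -dudr * d / r # force on i
      f[i, ] <- f[i, ] + fij
      f[j, ] <- f[j, ] - fij
    }
  }
  f
}
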