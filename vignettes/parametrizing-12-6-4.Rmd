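---
title: "Parametrizing the 12-6-4 nonbonded model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parametrizing the 12-6-4 nonbonded model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lj1264)
```

## The model

Standard fixed-charge force fields describe nonbonded interactions with a
12-6 Lennard-Jones term plus Coulomb electrostatics. For ions — divalent
metals especially — this misses the charge-induced-dipole attraction,
which falls off as $r^{-4}$. The 12-6-4 model adds that term explicitly:

$$U_{ij}(r) = \frac{C_{12}^{ij}}{r^{12}} - \frac{C_6^{ij}}{r^6}
            - \frac{C_4^{ij}}{r^4}
            + k_C\,\frac{Q_i Q_j}{\varepsilon r},$$

with $k_C = 332.0637$ kcal·Å/(mol·e²). Under this sign convention a
positive $C_4$ is attractive; tabulated negative values act as a repulsive
correction. Physically $C_4$ is tied to the polarizability $\alpha_0$ of
the partner atom — `c4_from_polarizability()` implements the
ion-induced-dipole relation $C_4 = k_C Q^2 \alpha_0 / 2$ — but in
parametrization practice $C_4$ is the primary fitted quantity and the
relation is only used to seed search brackets.

`lj1264` implements the free-energy-based workflow for fitting $C_4$
cross-terms: alchemical hydration free energies by thermodynamic
integration (TI), binding free-energy profiles by umbrella sampling plus
WHAM, and a bisection loop that tunes $C_4$ until a target free energy is
reproduced. Everything runs on built-in toy systems with analytic
oracles, so the full pipeline is testable on a desk.

## Sampling: Metropolis Monte Carlo instead of MD

Every observable in this package — $\langle dU/d\lambda\rangle$ averages,
window histograms, PMFs — depends only on the canonical equilibrium
distribution, not on dynamics. The samplers are therefore Metropolis
Monte Carlo chains: simpler than molecular dynamics, exactly seedable
(identical seed and configuration give bit-identical output), and free of
thermostat/barostat machinery. Proposals are single-particle uniform
displacements; default step sizes per system keep acceptance inside
[0.2, 0.8]. Defaults: 10% of the chain discarded as burn-in, thinning 10
for generic use; the free-energy pipelines record every step (thin = 1)
and absorb autocorrelation with blocked standard errors (block size 100)
instead, since the quadrature averages only need unbiased means.

The built-in systems are:

* **harmonic1d** / **doublewell1d** / **flat** — 1-d potentials with
  closed-form free energies, densities and extrema, used as oracles.
* **ion_pair_continuum** — a divalent cation and a singly charged ligand
  site on a 1-d separation coordinate in a dielectric continuum
  ($\varepsilon = 78.5$), with a tunable $C_4$. Its PMF is the potential
  itself, so every step of the umbrella/WHAM/binding pipeline has an
  analytic reference.
* **micro_solvation_box** — one charged solute bead plus 14 solvent beads
  in a periodic 12 Å box (NVT, minimum image, 6 Å truncation). The bath
  is deliberately dilute and weakly charged (±0.05 e, net neutral;
  solvent ε = 0.1 kcal/mol): single-particle Metropolis moves equilibrate
  such a bath well within the default burn-in, which we verified by
  chain-length stability of the computed free energies. A dense,
  strongly charged bath is glassy under local moves and its free
  energies drift for hundreds of thousands of steps — an honest sampler
  cannot use it at desk scale.

What the toys do *not* emulate: explicit hydrogen-bonded water structure,
NPT density fluctuations, long-range (Ewald) electrostatics, and
many-body polarization response. Passing tests therefore demonstrate the
correctness of the estimators and the fitting logic, not the accuracy of
any particular force field for real solutions.

## Thermodynamic integration and the λ schedule

The free-energy difference along an alchemical coupling is
$\Delta G = \int_0^1 \langle dU/d\lambda\rangle_\lambda\, d\lambda$,
evaluated by Gauss–Legendre quadrature mapped to $[0,1]$.
`gauss_legendre_unit(12)` gives the standard 12-window schedule
(0.00922, 0.04794, …, 0.99078); weights sum to one and the rule is exact
for polynomials up to degree $2n-1$. Nodes and weights are kept at full
precision internally; the 5-decimal presentation is applied only when
printing.

Soft-core decoupling removes the end-point catastrophe: the 12-6 part
becomes

$$V_{sc}(r;\lambda) = 4\varepsilon\lambda\left[\frac{1}{A^2} -
\frac{1}{A}\right],\qquad A = \alpha(1-\lambda) + (r/\sigma)^6,$$

with $\alpha = 0.5$ and $\sigma$ the zero crossing of the unmodified
potential. This is exactly the plain 12-6 energy at $\lambda = 1$, zero
at $\lambda = 0$, and finite at $r = 0$ for $\lambda < 1$.

Two cycle protocols are provided. The **two-step** (per-component)
protocol grows the legs in the order vdW → Pol ($C_4$) → Ele (charges);
the ordering is our choice — it keeps a repulsive core in place before
any bare attractive $r^{-4}$ or Coulomb term is switched on, so the
linear scaling of those tails in their own legs is safe. The **one-step**
protocol scales all components along a single λ; there a bare linear
$-\lambda C_4/r^4$ next to a soft vdW core would reintroduce the
singularity, so the $r^{-4}$ and $r^{-1}$ tails share the soft-core
denominator ($\propto A^{-2/3}$ and $A^{-1/6}$), which preserves both
endpoints and keeps $dU/d\lambda$ analytic. Both protocols share their
endpoints, so their totals agree by the state-function property — one of
the package's acceptance checks.

The gas-phase reference of a single-bead solute has no intramolecular
terms and is exactly zero, so the hydration free energy equals the
coupling free energy in the bath. Per-node standard errors come from
block averaging; the quadrature propagates them as
$\sqrt{\sum_i w_i^2 se_i^2}$. This package reports blocked standard
errors as its replicate-level uncertainty; the choice of estimator is
ours and is documented rather than inherited.

## Umbrella sampling and WHAM

Windows are planned as evenly spaced harmonic restraints
($U_b = \tfrac12 k (r - r_0)^2$) covering the coordinate range;
`check_overlap()` quantifies adjacent-window histogram overlap (the
overlap coefficient, validated against the closed-form Gaussian value)
and flags pairs below 0.05 — the operational form of the requirement
that neighboring windows overlap.

`wham_solve()` iterates the standard two-equation WHAM system on shared
histograms until the largest change in the window offsets falls below
the tolerance. Numerical choices, all ours (the upstream protocol leaves
them unstated): bin width 0.05 Å (fine enough for sub-Å landmark
structure), offset tolerance $10^{-7}$ kcal/mol, iteration cap $10^5$,
bins with fewer than 10 raw counts reported as gaps rather than
extrapolated. The solver is deterministic given its inputs;
non-convergence is an error carrying the residual, never a silent
result.

The binding free energy is read off the profile as (global minimum in
the bound region) − (mean over the unbound plateau); the plateau
defaults to the outermost 15% of the sampled range and a fitted slope
steeper than 0.1 kcal/(mol·Å) attaches a warning. A 1-d standard-length
correction ($-k_BT\ln(w_{\mathrm{eff}}/1\,\text{Å})$, with
$w_{\mathrm{eff}}$ the thermally weighted bound-well width) is computed
and reported separately — never silently added, since the calculated
values are compared directly with experimental $\Delta G_{bind} = -RT\ln
K_a$ (298 K, $R = 1.9872\times10^{-3}$ kcal/(mol·K)).

Landmarks (minima/barriers) are detected on a 3-bin moving-average
smoothed copy with alternation enforced; extrema within a few bins of
the profile ends are discarded as edge artifacts, and adjacent
landmark pairs separated by less than a prominence threshold (default
0.1 kcal/mol, a few times the bin-level noise of a well-sampled
profile) are pruned as statistical wiggles. The stored profile itself
is never smoothed, and landmark heights are read from the unsmoothed
bins.

## Fitting C4

`fit_c4()` is a bisection on $C_4$ with common random numbers: every
candidate is evaluated with the same fixed replicate seeds (three by
convention, mirroring a Rep #1–#3 protocol), which makes the objective a
deterministic function of $C_4$ and a 1-d monotone bisection well posed.
Before bisecting, the objective is scanned at five points across the
bracket and must be monotone within noise (3× the replicate standard
error) — a guard for the monotonicity assumption the whole approach
rests on — and the bracket must straddle the target. Success requires
the replicate mean within the target tolerance: 0.05 kcal/mol for TI
hydration targets and 0.30 kcal/mol for PMF binding targets, the
agreement levels these two observables support. The replicate mean (not
a single run) is the fitted criterion; replicate statistics use the
sample (n−1) standard deviation, and 2-decimal rounding happens only at
presentation.

Missing experimental reference values are handled by ordinary
least-squares extrapolation of computed-vs-experimental pairs
(`fit_regression()` / `extrapolate()`); with exactly two points the line
interpolates both.

## Problem sizes and reproducibility

The shipped pipelines use 19 umbrella windows × 5×10⁴ recorded samples
for binding objectives and 12 λ nodes × 10⁵ recorded samples for TI
objectives; these sizes give replicate-mean uncertainties comfortably
inside the fitting tolerances on the toy systems and are the sizes the
test suite and the reproduction script use. Every workflow consumes a
single master seed from which per-window/per-node sub-seeds are derived,
so any run is reproducible from its configuration alone.

## Known limitations

* The toys are 1-d or few-particle caricatures; no claim is made about
  explicit-solvent accuracy, and the package deliberately does not
  reproduce published absolute $C_4$ values, which are tied to
  full-scale explicit-water simulations.
* Plain cutoff truncation only (no Ewald/PME, no long-range
  corrections); periodic electrostatics beyond minimum-image truncation
  are out of scope.
* The Gauss–Legendre rule is accurate for smooth integrands but has no
  built-in error estimate; comparing protocols (one-step vs two-step)
  and orders is the practical check.
* `fit_c4` assumes a monotone objective on the bracket; the pre-scan
  guard detects gross violations but cannot prove monotonicity between
  scan points.
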