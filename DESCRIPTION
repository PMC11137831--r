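Package: lj1264
Title: Parametrization Toolkit for the 12-6-4 Lennard-Jones Nonbonded Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for parametrizing the 12-6-4 Lennard-Jones nonbonded model
    used for divalent metal ions and ionized ligands: pairwise 12-6-4 plus
    Coulomb energies with the ion-induced-dipole C4 cross-term, soft-core
    alchemical decoupling, thermodynamic integration over a Gauss-Legendre
    lambda schedule with one-step and two-step hydration-free-energy cycles,
    umbrella sampling with WHAM reconstruction of binding free-energy
    profiles, and bisection fitting of C4 cross-terms against target
    hydration or binding free energies. All workflows run on built-in
    Metropolis Monte Carlo toy systems with analytic oracles, so the full
    parametrization pipeline is exercisable offline at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
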