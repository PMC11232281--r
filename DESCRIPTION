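Package: hemeCoop
Title: Redox Cooperativity in Multiheme Cytochromes by Continuum
    Electrostatics, Microstate Monte Carlo and Marcus Kinetics
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies redox cooperativity between heme cofactors in
    designed and natural multiheme cytochromes. Reads protein structures
    with heme groups, auto-detects heme type and axial ligation, estimates
    the interior dielectric constant from heme solvent exposure, and solves
    the linearized Poisson-Boltzmann equation on a focused finite-difference
    grid with an optional implicit membrane slab to obtain per-heme
    oxidation energies and heme-heme oxidation interaction energies. These
    terms feed a joint proton/electron microstate Hamiltonian sampled by
    exact enumeration or Metropolis Monte Carlo titration, with Nernst
    fitting of the resulting curves, decomposition of the redox-potential
    splitting into environmental and heme-heme contributions, and
    non-adiabatic Marcus electron-transfer rates with steady-state hopping
    redox currents. Includes a synthetic four-helix-bundle fixture
    generator so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Rcpp,
    jsonlite,
    yaml,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
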