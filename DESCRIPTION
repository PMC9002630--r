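Package: spinmix
Title: Spin Dynamics Simulation of Solid-State NMR 13C Homonuclear Mixing
    under Magic-Angle Spinning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Density-matrix simulation of polarization transfer through 13C
    side chains of methyl-bearing amino acid residues under magic-angle
    spinning (MAS). Generates exact piecewise-constant RF programs for the
    common first-order homonuclear mixing schemes (TOBSY C9 symmetry
    sequences with POST elements, WALTZ-16, DIPSI-3, FLOPSY-16, finite-pulse
    RFDR with xy8 phase cycling, and adiabatic-sweep DREAM), assembles the
    secular rotating-frame Hamiltonian of small spin systems (chemical shift
    offsets, CSA, scalar and dipolar couplings) under sample rotation at the
    magic angle, propagates the density operator with a fast, exactly unitary
    split-operator integrator, and powder-averages transfer efficiencies over
    REPULSION or ZCW crystallite sets. Includes built-in alanine and leucine
    model spin systems, buildup-curve analysis, MAS-frequency and static-field
    scans, RF-inhomogeneity and resonance-offset robustness maps, and
    comparison of branched versus isotopically linearized side-chain
    topologies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    bio3d,
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
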