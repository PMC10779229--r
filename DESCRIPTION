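Package: hvgating
Title: Gating-Current Simulation and Charge-Trapping Analysis for
    Voltage-Gated Proton Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the quantitative analysis of voltage-sensor gating
    currents in Hv1-type proton channels. Simulates N-state voltage-dependent
    Markov gating schemes exactly by eigendecomposition of the master-equation
    generator, integrates ON/OFF gating charge from current sweeps, fits
    single- and double-exponential kinetics and two-state Boltzmann Q(V)
    relations, converts Boltzmann parameters to activation free energies,
    and post-processes coordinate trajectories for salt-bridge distances,
    occupancies, z-density profiles, Coulombic triad energies with a
    thermodynamic-cycle comparison, and RMSD-based conformational clustering.
    Includes a synthetic-data generator with known ground truth for
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    bio3d,
    jsonlite,
    minpack.lm,
    graphics,
    pracma,
    stats,
    utils,
    withr
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
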