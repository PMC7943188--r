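Package: kvgating
Title: Voltage-Clamp Gating Analysis for Shaker-Type Potassium Channels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for cut-open-oocyte voltage-clamp studies of
    voltage-gated potassium channel gating. Reduces raw current sweeps to
    per-cell measurements (peak currents, conductances, time-integrated gating
    charge, biexponential inactivation fits), builds normalized cohort-averaged
    G-V, Q-V, Inac-V and I-V curves, fits two-state and three-state Boltzmann
    gating models, converts fitted parameters and median charge-movement
    voltages into activation free energies, and evaluates residue-residue
    coupling by thermodynamic mutant-cycle (generalized interaction-energy)
    analysis. A seeded synthetic-sweep generator emulates the statistical
    structure of oocyte recordings so every stage is testable without
    experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    pracma,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
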