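Package: pbpka
Title: Ensemble Poisson-Boltzmann pKa Calculations and pH-Sensor Analysis
    for Membrane Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Iterative, ensemble-based prediction of side-chain pKa values
    in membrane proteins from structural snapshots, using a linearized
    finite-difference Poisson-Boltzmann solver with an implicit membrane
    slab dielectric (distinct permittivities for membrane core, headgroups,
    protein interior and solvent), per-frame membrane geometry estimation,
    explicit treatment of bound ions, grid focusing, and a thermodynamic
    cycle against a solvated model compound. Downstream tools rank
    candidate pH sensors from state-dependent pKa tables, compute
    Henderson-Hasselbalch protonation fractions across gating transitions,
    classify drivers versus stabilizers, fit pH dose-response curves to the
    Hill equation, evaluate double-mutant-cycle additivity, and regress
    midpoint shifts against side-chain property scales. A synthetic-data
    module generates toy membrane systems, jittered frame ensembles, and
    simulated electrophysiology tables so that the entire pipeline can be
    exercised without external inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
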