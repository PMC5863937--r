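Package: hcn2kinetics
Title: Markov Kinetic Modelling of Voltage-Dependent HCN2 Channel Gating
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constrained Markov state models of voltage-dependent activation
    gating in HCN2 pacemaker channels and its modulation by cAMP. Provides
    kinetic schemes with Eyring-type voltage-dependent rate laws, microscopic
    reversibility and saturating-open-probability constraints, master-equation
    propagation through piecewise-constant voltage protocols, computed
    observables (state occupancies, probability flux densities, per-channel
    gating currents and moved gating charge, Boltzmann activation curves),
    global multi-trace least-squares fitting with parameter standard errors
    and model ranking, and a synthetic-data generator emulating averaged
    double-pulse open-probability recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    minpack.lm,
    Matrix,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
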