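Package: membrafluor
Title: Steady-State Fluorescence Analysis of Membrane Order, Phase
    Transitions and Lipid Peroxidation
Version: 0.1.0
Authors@R: person("Membrafluor", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis toolkit for steady-state fluorescence assays of lipid
    membranes: DPH fluorescence anisotropy melting curves with two-stage
    transition-temperature extraction (Boltzmann sigmoid fit, analytic first
    derivative, Lorentzian peak fit for T_m and peak width), Laurdan
    generalized polarization, TEMPO quenching of DPH for liquid-ordered
    raft-fraction estimation, and cis-parinaric acid peroxidation kinetics
    with endpoint and kinetic antioxidant protection factors. Includes seeded
    forward simulators for every input modality with ground-truth manifests,
    replicate statistics (paired t, Tukey HSD), delimited-text readers and
    writers, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
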