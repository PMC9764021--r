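Package: kirtraj
Title: Trajectory Analysis and Kinetic Simulation of Inward-Rectifier
    Potassium Channel Permeation, Gating, and Polyamine Block
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyzers for molecular-trajectory studies of inward-rectifier
    potassium (Kir) channels: permeation-event detection with hysteresis
    thresholds, single-channel current and conductance, kinetic site
    occupancies, water-to-ion co-permeation ratios, axial densities,
    residence times, and knock-on configuration histograms; activation-gate
    geometry, cavity-hydration and pore-closure detection with censored
    survival summaries; spermine blocker bind/unbind kinetics (running-median
    distance criteria, censored exponential tau estimation, station
    classification, displaced-ion counts); and a CMAP-style backbone
    torsional-correction generator for selectivity-filter stabilization.
    Includes an exact-jump (Gillespie) kinetic trajectory generator for
    single-file, voltage-biased ion hopping through the extended pore with a
    two-state gate and a voltage-dependent polyamine blocker, emitting
    pseudo-atom trajectories with exact ground-truth event logs for analyzer
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    survival,
    tools,
    utils,
    yaml
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
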