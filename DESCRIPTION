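Package: smartinsole
Title: Capacitive Smart-Insole Sensor Characterization and Plantar-Pressure Gait Analysis
Version: 0.1.0
Authors@R:
    person("Insole", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis chain for a 16-channel capacitive
    plantar-pressure insole. Provides a physics-based model of a single
    3D-printed capacitive pressure sensor (series two-dielectric capacitance,
    linear pressure transduction with a hysteretic unloading branch, asymmetric
    first-order response dynamics), generators for dynamic-loading rig
    protocols (pressure staircases, constant-pressure cadence sweeps,
    durability runs, quasi-static hysteresis ramps) and for synthetic gait
    cycles with ground-truth phase labels, the standard sensor-characterization
    metrics (sensitivity and linearity, degree of hysteresis, 10-90 percent
    response and recovery times, loading-frequency invariance, durability
    drift), and a plantar-pressure pipeline (capacitance-to-pressure
    calibration, center-of-pressure trajectories, a 227-cell pressure heatmap,
    rule-based gait-phase segmentation, per-zone peak summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
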