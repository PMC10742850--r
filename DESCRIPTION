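Package: extrurtd
Title: Residence Time Distribution Analysis and Image-Based Texture
    Prediction for Twin-Screw Extrusion
Version: 0.1.0
Authors@R:
    person("Process Analytics", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for pulse-tracer residence time distribution (RTD)
    analysis of twin-screw extrusion: exit-age and cumulative
    distributions E(t)/F(t), mean residence time, variance,
    dimensionless curves, and the closed-vessel axial-dispersion Peclet
    number obtained by inverting the dispersion relation.  Also provides
    an image-feature based texture-quality workflow: CIELAB colour and
    grey-level co-occurrence contrast extraction from product
    photographs, a single-hidden-layer backpropagation regressor whose
    initial weights can be chosen by particle swarm optimisation or a
    real-coded genetic algorithm, and MAE/RMSE/MAPE evaluation.
    Synthetic generators for tracer curves and feature/texture tables
    make the full pipeline testable without an extruder or texture
    analyzer.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
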