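Package: reflexgait
Title: Predictive Planar Gait Simulation with Reflex-Based Muscle Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward ("predictive") simulation of human walking with a planar
    9-degree-of-freedom musculoskeletal model driven by 18 Hill-type
    muscle-tendon actuators and a reflex-based gait controller. Gait emerges
    de novo by optimizing the controller's gains, offsets, state-machine
    thresholds and the model's initial state with a rank-mu CMA-ES
    single-shooting strategy against a four-term objective (cost of transport,
    step-speed window, ligament injury, head stability). Includes plantarflexor
    weakness and contracture transforms, Umberger-style muscle energetics,
    compliant Hunt-Crossley foot-ground contact, and a gait-analysis layer
    (step segmentation, spatiotemporal measures, cycle normalization, RMSE in
    SD units, normalized cross-correlation, Z-score panels) for validation
    against normative bands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
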