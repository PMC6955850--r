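Package: tavsurrogate
Title: Machine-Learning Surrogates for Transcatheter Aortic Valve Leaflet Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parametric geometry and deep-network surrogate modelling for
    transcatheter aortic valve (TAV) leaflet design. From three leaflet design
    parameters (attachment-curve coefficient a, suturing-line shape coefficient
    b, and stent suturing line length SSL) the package builds the 2D scallop
    leaflet contour and a fixed-topology triangulated mesh, evaluates a
    fiber-reinforced hyperelastic (modified Gasser-Ogden-Holzapfel) strain
    energy for porcine pericardium, and generates deterministic pseudo
    finite-element fields (deformed 3D nodal coordinates and in-plane stress
    components S11, S22, S12) with the structure real valve-closure simulations
    produce. Two surrogate families map design parameters to full nodal fields:
    an autoencoder-based model (design parameters to an 8-number field code to
    the field) and a direct feedforward model, both trained with Adamax and
    mean-squared-error loss. Monte-Carlo cross-validation with the field's
    standard shape and stress error metrics (MeanE, NMeanE, MaxE, NMaxE),
    a mean-predictor baseline, VTK export for ParaView, and a command-line
    interface complete the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    arrow,
    jsonlite,
    lhs,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
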