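Package: facefem
Title: Probabilistic Finite-Element Prediction of Facial Soft-Tissue Position
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Probabilistic quasi-static viscoelastic finite-element modelling of
    midface soft-tissue response to Le Fort I maxillary advancement. Provides a
    synthetic layered midface phantom with osteotomised bone, cartilage inclusion
    and near-incompressible soft tissue; a linear tetrahedral solver with
    Prony-series shear relaxation and B-bar volumetric treatment; Latin-hypercube
    designs of experiments with Spearman variable screening; response-surface
    surrogates and multi-objective genetic optimisation of material properties
    against observed landmark displacements; Weibull fitting of the optimised
    candidates; and a two-iteration pipeline that returns per-landmark prediction
    envelopes (minimum, maximum, histogram, cumulative density) instead of a
    single deterministic prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    lhs,
    kernlab,
    fitdistrplus,
    stats,
    utils,
    tools,
    grDevices,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
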