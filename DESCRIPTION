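Package: dendritespt
Title: Single-Particle Tracking and Spatial Analysis of Vesicle Traffic in
    Dendrites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse the motion of fluorescently
    labelled receptor-carrying vesicles in neuronal dendrites. Provides a
    synthetic-data generator (dendrite geometry, Markov-switching vesicle
    motion, stochastic tetramer photobleaching, exocytosis events and
    rendered fluorescence movies), particle detection by 2D Gaussian
    fitting with multi-target linking, hidden Markov motion-state
    inference (diffusion versus directed transport) with BIC model
    selection, mean-squared-displacement model fitting, vesicle
    classification filters, dendrite-referenced spatial statistics
    (zones, confinement radius, directional bias, photobleach-adjusted
    counts, exocytosis linkage), filamentous-actin skeleton
    quantification, and a small reporting layer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    tiff,
    mgcv,
    minpack.lm,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
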