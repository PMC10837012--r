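Package: wormmodes
Title: Behavioral Module Discovery from Worm Posture and Muscle Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes Caenorhabditis elegans male mating behavior into
    stereotyped modules from simultaneous posture and muscle-activity
    recordings. Provides midline-based posture quantification (19 signed
    bending angles over 20 equal body segments) together with ratiometric
    GCaMP/mDsRed muscle-activity measurement, model-free temporal analyses
    (autocorrelation, Welch spectral density, penalized changepoint
    segmentation), Bayesian fitting of a sticky autoregressive hidden
    Markov model by Gibbs sampling with self-transition bias tuning,
    module characterization statistics (usage frequencies, speed and
    curve-shape histograms, in-block versus among-block percentile
    variance, skeleton overlays, vulva-contact classification), bi-module
    repeat syntax analysis, and a seeded synthetic-recording generator so
    the whole pipeline can be exercised end to end without video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
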