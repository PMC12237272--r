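Package: freqdisc
Title: Auditory Tuning, Spike-Train Discriminability and Population Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for Go/No-Go auditory psychophysics and
    tone-evoked extracellular recordings: peristimulus time histograms and an
    evoked-response criterion, six-parameter rate-level-function fits with
    derived threshold and gain, frequency-response-area metrics (characteristic
    frequency, minimum threshold, bandwidth and Q-values), rate-independent
    SPIKE-distance spike-train discriminability, and an experimentally informed
    Bayesian population decoder with a censored-Poisson readout that links
    cortical tuning parameters to frequency-discrimination performance. A
    seeded synthetic-data module generates Poisson spike trains on a
    frequency-by-intensity grid and behavioral sessions so every stage is
    testable without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    minpack.lm,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
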