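Package: mubeta
Title: Oscillatory and Aperiodic Features of the Sensorimotor Mu-Beta Rhythm
Version: 0.1.0
Authors@R:
    person("Mubeta", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies resting-state sensorimotor cortical activity from
    single-channel region-of-interest time series: Welch power spectral
    density, decomposition into an aperiodic (1/f) component plus Gaussian
    oscillatory peaks in the alpha (8-12 Hz) and beta (13-30 Hz) bands,
    and detection of transient mu-beta (8-30 Hz) burst events from the
    Hilbert envelope of the band-passed signal. Includes Bayesian
    regression analyses of the extracted features (Gaussian and Poisson
    models with BIC-approximated Bayes factors), a synthetic signal and
    cohort generator with known ground truth for end-to-end validation,
    and a reproducible command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    MASS,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
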