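Package: dyadsync
Title: Dyadic EEG Frontal Alpha Asymmetry and Lagged Concordance Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for EEG hyperscanning studies of dyads: preprocessing of
    time-locked continuous two-person EEG (bandpass filtering, correlation-based bad-channel
    rejection, spectral-threshold artifact rejection, neighbor interpolation, average
    reference), frontal alpha asymmetry (FAA) time courses from 500 ms epochs, within-dyad
    concurrent and lagged concordance correlation coefficients (CCC) on 2 s bins, and linear
    mixed-effects models of condition and time effects with estimated marginal means, trend
    extraction, FDR-corrected contrasts, and individual-difference correlations. Includes a
    synthetic dyadic-EEG generator with a latent coupled FAA driver so every stage is
    verifiable against ground truth, and a minimal EDF reader/writer for interchange.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    emmeans,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
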