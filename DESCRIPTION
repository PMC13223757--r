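Package: netsegfc
Title: Resting-State Network Segregation and Behavioral Association Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking resting-state functional-connectivity network
    segregation to behavioral outcomes. Implements framewise-displacement
    motion censoring (filtered FD thresholding, contiguity and run-length
    rules, fixed-frame selection), ROI time-series denoising (detrending,
    nuisance regression, censored-frame interpolation, temporal band-pass),
    Fisher-z connectivity matrices with within/between-network and
    segregation metrics over a 300-ROI 14-network parcellation, and an
    association-model layer with FDR correction across networks, augmented
    backward elimination by AIC, and bootstrap model-stability diagnostics.
    A synthetic-cohort generator with planted network covariance, motion
    spikes, and behavioral effects provides a recoverable ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    signal,
    jsonlite,
    yaml,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
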