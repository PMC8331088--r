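Package: microstate
Title: Resting-State EEG Microstate Analysis with a Synthetic Cohort Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation of resting-state EEG into microstates and group-level
    statistics of their temporal dynamics. Provides global field power (GFP)
    computation and peak extraction, polarity-invariant atomize-and-agglomerate
    hierarchical clustering (AAHC) at the individual and group level, canonical
    A-D template labeling, spatial-correlation backfitting with inter-peak
    interpolation, temporal parameters (duration, occurrence, coverage) and
    global explained variance (GEV), topographic randomization tests (TANOVA)
    on global map dissimilarity, t-tests and FDR-corrected clinical
    correlations. A semi-Markov synthetic-EEG cohort generator with known
    ground truth supports end-to-end validation of the whole pipeline,
    emulating healthy-control and Parkinson's disease (DBS-OFF/DBS-ON) groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
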