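Package: nocicode
Title: Population Coding of Acute Pain Intensity in Cortical Spike Trains
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of how acute-pain intensity is encoded by populations
    of simultaneously recorded cortical neurons, and how a chronic
    inflammatory pain state degrades that code. Provides trial-aligned
    peristimulus time histograms with baseline z-scoring, a two-part
    threshold criterion for pain-responsive units, cumulative-window
    population decoding with a support-vector-machine classifier and
    permutation-based chance levels, robust-regression intensity tuning
    curves with slope comparison, conditioned-place-aversion scoring with
    baseline exclusion, and Dixon up-down estimation of 50% mechanical
    withdrawal thresholds. Includes an inhomogeneous-Poisson synthetic
    spike-session generator and behavioral cohort simulators for
    calibration and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    MASS,
    e1071,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'io.R'
    'synthgen.R'
    'psth.R'
    'responsive.R'
    'decoding.R'
    'tuning.R'
    'behavior.R'
    'pipeline.R'
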