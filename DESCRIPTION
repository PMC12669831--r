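Package: hillnet
Title: Hill-Type Muscle Models Versus Neural-Network Muscle Force Estimators
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to compare per-timepoint feed-forward neural-network
    estimators of muscle tendon force against a Hill-type muscle model whose
    six parameters are fitted by covariance matrix adaptation evolution
    strategy (CMA-ES). Includes the electromyography preprocessing chain
    (zero-phase Butterworth filtering, rectification, envelope extraction,
    peak-based activation scaling, excitation-contraction delay), a
    synthetic-data generator emulating in vivo avian gait recordings
    (cyclic activation bursts, fascicle length oscillations, ground-truth
    Hill forces with optional history dependence), bespoke evaluation
    metrics (peak detection, peak matching, rise and fall times, relative
    RMSE), and force-length / force-velocity curve probing of trained
    estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    numDeriv,
    optparse
Config/testthat/edition: 3
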