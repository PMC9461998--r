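Package: surpn400
Title: Speaker-Based Surprisal Modelling of Single-Trial N400 Amplitudes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying how listeners adapt their predictive language
    models to the statistics of individual speakers. Builds adjective-cluster
    bigram language models from word embeddings and corpus counts, computes
    global and incremental per-speaker surprisal, generates the counterbalanced
    two-speaker experiment designs, derives resting-EEG individual-difference
    metrics (aperiodic 1/f slope via irregular-resampling auto-spectral
    analysis, individual alpha frequency), extracts single-trial prestimulus
    and N400 window amplitudes, and fits crossed variance-components linear
    mixed models with partial-effect extraction. A synthetic-data generator
    with known ground truth supports parameter-recovery and calibration
    studies of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    mclust,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
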