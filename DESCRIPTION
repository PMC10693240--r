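Package: antiphony
Title: Turn-Taking and Latency-Matching Analysis for Interactive Acoustic Playback
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing vocal turn-taking between a live subject and an
    interactively controlled playback system, built around annotated acoustic
    event tables (Raven selection-table dialect). Computes inter-call latencies
    (preceding call offset to subsequent call onset), classifies counter calls,
    extracts exemplar-subject response pairs and their standardized latency-ratio
    shares, fits negative binomial, logistic and Gaussian regressions on the
    resulting datasets, and assesses significance with seeded randomization
    tests. Includes a coupled-oscillator session simulator with known ground
    truth for parameter-recovery and calibration experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
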