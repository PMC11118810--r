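Package: mnstate
Title: Motor-Network State-Dependent TMS-EEG Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Source-space analysis of pre-stimulus motor-network phase
    coupling and its relation to TMS-evoked motor potentials. Implements
    seed-based connectivity at the individual mu-rhythm frequency using the
    imaginary part of the phase-locking value (iPLV), eLORETA spatial
    filtering, median-split connectivity-state analysis of MEP amplitude,
    multivariate phase-slope-index directionality with jackknife pseudo-Z
    scores, autoregressive pre-pulse phase prediction, and robust-regression
    model comparison by AIC. A synthetic EEG/EMG session generator with
    known coupling, phase and MEP ground truth makes every stage testable
    without access to experimental recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    Rcpp,
    dplyr,
    ggplot2,
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
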