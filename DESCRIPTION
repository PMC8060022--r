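Package: anklepref
Title: Adaptive Forced-Choice Estimation of Preferred Prosthetic Ankle Alignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying a prosthesis user's preferred ankle
    alignment with a Bayesian adaptive two-alternative forced-choice
    procedure, and for processing the gait sensor streams (pylon load cell,
    socket force-sensing resistors, inertial measurement unit) used to
    characterize why preferences arise. Includes a cumulative-normal
    psychometric model with fixed lapse rate fit by maximum likelihood, a
    grid-based adaptive stimulus-selection engine that minimizes expected
    posterior entropy, Monte-Carlo design-evaluation utilities, a
    complementary-filter shank-pitch estimator, stride segmentation and
    gait-cycle normalization, pressure-time integrals, and a fully seeded
    synthetic-data generator so the entire pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    signal,
    pracma,
    generics,
    withr
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
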