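Package: fitfatigue
Title: Fitness-Fatigue Impulse-Response Modelling of Walking Rehabilitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying structured home-based walking exercise as
    training impulses (TRIMPs) and for calibrating the Banister two-component
    (fitness-fatigue) impulse-response model against sparse clinic-visit
    measurements of walking performance in peripheral artery disease.
    Includes per-session TRIMP computation from cadence-based prescriptions,
    discrete-convolution performance prediction, per-subject nonlinear
    least-squares calibration with a profiled grid search, detraining decay
    estimation, method-agreement statistics (Passing-Bablok regression,
    intraclass correlation, paired t-tests), a synthetic cohort generator
    emulating a test-in train-out (TiTo) rehabilitation protocol, and an
    end-to-end reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
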