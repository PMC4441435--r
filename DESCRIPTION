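Package: aptperf
Title: Performance Assessment of Whole-Lake Acoustic Positional Telemetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for assessing the performance of
    whole-lake acoustic positional telemetry (APT) systems. Provides a
    synthetic-data generator emulating hydrophone arrays, habitat-dependent
    acoustic detection and multipath outliers in small lakes; a hyperbolic
    (time-difference-of-arrival) multilateration solver with per-fix quality
    metrics (dilution of precision, condition number, redundancy); quality
    filtering and grid-based hidden Markov model track smoothing with
    t-distributed observation noise; per-trial performance statistics
    (efficiency, accuracy, precision, false movement, tow-track length bias);
    and generalized least squares models of performance against habitat
    category with heterogeneous variances, baseline-shifting post-hoc
    contrasts and back-transformed summaries.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    stats,
    mgcv,
    pracma,
    yaml,
    jsonlite,
    xml2,
    generics,
    withr
Suggests:
    testthat (>= 3.0.0),
    nlme,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
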