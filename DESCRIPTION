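Package: cddfip
Title: Overlapping Dynamic Functional Connectivity States via Constrained Two-Stage ICA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates overlapping, subject-specific dynamic functional network
    connectivity (dFNC) states from network timecourses. Sliding-window Pearson
    correlation yields windowed connectivity matrices; blind ICA on the
    concatenated, demeaned windows extracts group-level independent connectivity
    states; constrained back-reconstruction against those priors gives
    subject-specific states, and a joint calibration regression restores the
    original correlation scale of each subject's state timecourses. From the
    calibrated mixing matrix the package computes dominant-state occupancy,
    pairwise amplitude convergence/divergence fractions, state dispersion
    profiles, and dynamic state density, with cellwise two-sample group
    statistics under Benjamini-Hochberg false-discovery-rate control. A
    synthetic-cohort generator with planted group effects makes the whole
    pipeline testable without imaging data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
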