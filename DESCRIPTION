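Package: cylsfm
Title: Bi-Stable Structure-from-Motion Cylinder Task Simulation and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the rotating-cylinder structure-from-motion (SFM)
    bi-stable perception paradigm used in visual psychophysics and
    computational psychiatry. Generates the stimulus dot kinematics and the
    real-switch control schedule, simulates synthetic observer cohorts with
    gamma-renewal percept dynamics, scores keypress event streams (real-switch
    accuracy and exclusion, percept durations, switch rates), and runs the
    group-level statistical battery (Kruskal-Wallis, Kolmogorov-Smirnov,
    ICC(3,k) test-retest reliability, Spearman symptom and metabolite
    correlations) with tidy outputs and ggplot2 figures.
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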