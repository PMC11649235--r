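Package: scsflight
Title: Defensive Ethogram Analysis for Serial-Compound-Stimulus Conditioned Flight
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds pip-level stimulus schedules for serial compound stimulus
    (SCS) fear-conditioning and extinction sessions, segments freezing, darting
    and escape-jump bouts from centroid tracking time series, computes trial-
    and period-level behavioral metrics (percent freezing, activity index,
    distance traveled, peri-stimulus event histograms, difference scores and
    cohort percentages), and runs the standard statistical battery (Welch t,
    one- and two-way ANOVA with Tukey post hoc) on the resulting metric tables.
    Includes a seeded behavioral-state trajectory simulator that emulates the
    group-, period- and trial-dependent structure of the conditioned-flight
    paradigm so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    car,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
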