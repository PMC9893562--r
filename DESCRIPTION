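Package: wheelmetrics
Title: Automated Micro-Analysis of Rodent Wheel-Running Behavior and
    Longitudinal Biomarker Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to turn raw running-wheel switch-closure timestamp streams
    into behavioral micro-analysis metrics (bouts, daily distance, running
    rate, run length, number of runs), aggregate them into birth-synchronized
    10-day medians, detect cessation of running by one-sample t-tests against
    zero, and relate running behavior to longitudinal disease biomarkers via
    percent change from baseline, factorial mixed-effects models and
    mixed-model-based partial correlations. Includes a stochastic cage
    simulator that generates bout-structured, night-locked event streams and
    linked biomarker panels so that every stage of the pipeline can be
    validated without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
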