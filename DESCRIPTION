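Package: weightrx
Title: Energy-Balance Weight Trajectories, Adherence Zones, and
    Automated Weight-Management Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A virtual weight-management clinic built around a
    two-compartment dynamic energy-balance model.  Predicts individual
    weight-change trajectories from demographics and an energy-intake
    prescription, inverts the model to estimate energy intake from
    longitudinal daily weights, cleans self-weighing telemetry
    (first-of-day rule, foreign-weight filter), quantifies dietary
    adherence via a zone around the predicted trajectory with
    color-coded daily flags, tracks daily step goals, and drives an
    escalating toolbox of behavioral strategies with scheduled tips,
    automated feedback events, and usage/outcome reporting.  Includes a
    synthetic-client telemetry generator so the whole pipeline can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    ggplot2,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
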