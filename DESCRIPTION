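Package: wardsim
Title: Stochastic Simulation of Resource-Dependent Maternal Mortality in a
    Referral Maternity Ward
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discrete-time (15-minute cycle) stochastic simulator of a
    low-resource maternity ward: shift-dependent patient admission, assignment
    of potentially life-threatening complications with truncated-normal
    severity distributions, priority-based (triage) allocation of nurses,
    doctors and medicines to treatment plans, geometric improvement under
    treatment and gamma-function deterioration without it, medicine restocking,
    calibration of treatment efficacies and deterioration rates to target case
    fatality rates, and batch scenario sweeps over medicine stocks, staffing
    grids, shift patterns and patient influx. Results are returned as tidy
    tibbles with broom-style tidy()/glance() methods and ggplot2-based plots.
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
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
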