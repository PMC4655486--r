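Package: neophron
Title: Individual-Based Population Model of Egyptian Vultures Limited by
    Rabbit Carrion and Griffon Competition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic individual-based simulation of an Egyptian vulture
    (Neophron percnopterus) breeding population whose carrying capacity is set
    by wild-rabbit carcass biomass inside a protected area and by carcass
    interception from an expanding griffon vulture population. The daily
    feeding and park-exit processes, monthly natural and poisoning mortality,
    and annual exit-dependent reproduction are executed as synchronized
    process modules. Includes calibration of the poisoning hazard,
    food-supply and competition coefficients to stated vital rates, hindcast
    and projection ensembles with Monte Carlo intervals, factorial and
    Box-Behnken scenario designs with quadratic response-surface fits,
    recovery-threshold extraction by bisection, and paired common-random-number
    parameter sensitivity analysis.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
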