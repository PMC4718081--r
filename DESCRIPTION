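Package: minibalance
Title: Mini Crosstalk-Network Balance Modelling of Alzheimer's Disease
    Progression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the crosstalk between the three core cerebrospinal-fluid
    biomarkers of Alzheimer's disease (amyloid-beta, tau, and
    phosphorylated tau) as a small transit-compartment network and scores
    disease progression through network imbalance.  Provides integral
    disruption parameters (squared distance U, modulus ratio K, and angle
    phi between a pathological and a normal marker vector), balance-map
    coordinates, adaptive Monte Carlo estimation of network disruption
    probability with a relative-error stopping rule, single- and
    joint-marker contribution analysis, and downstream evaluation by
    least-squares regression against MMSE and cross-validated support
    vector machine classification.  A configurable generator of synthetic
    ADNI-like longitudinal cohorts makes the whole pipeline reproducible
    without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    e1071,
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
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
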