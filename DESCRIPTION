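Package: breathkin
Title: Dynamic Breath Washout Kinetics and Diagnostic Evaluation for
    Exogenous Volatile Probes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of dynamic breath-test studies that use an
    ingested volatile probe (limonene) to read out hepatic first-pass function.
    Provides a synthetic cohort generator with a flow-limited one-compartment
    oral-dose model, portosystemic shunting and limit-of-quantification
    censoring; non-compartmental kinetic analysis (Cmax, Tmax, terminal
    log-linear slope and intercept, trapezoidal AUC); per-timepoint diagnostic
    evaluation by logistic scoring with repeated stratified splits, ROC/AUROC
    and Youden operating points; canonical correlation of breath bioavailability
    against clinical liver scores; and Mann-Whitney and random-intercept
    mixed-model inference, with a reproducible end-to-end pipeline.
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
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
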