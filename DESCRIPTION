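Package: futilitymon
Title: Futility Monitoring for Group-Sequential Clinical Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for interim futility monitoring of randomized clinical
    trials on the Brownian-motion (B-value) scale: conditional power under
    the design hypothesis or the current trend, reverse conditional power,
    predictive probability of success under a normal prior on the drift,
    operating characteristics of stochastic-curtailment rules, alpha- and
    beta-spending boundary derivation with drift calibration by recursive
    numerical integration, predicted intervals and predicted-interval plots
    for binary and time-to-event endpoints, and Monte-Carlo simulation of
    monitored trial paths.
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
    pracma,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
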