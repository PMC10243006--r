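Package: survcloak
Title: Privacy-Enhancing Survival Curves for Federated Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds disclosure-controlled Kaplan-Meier survival curves for
    per-site (federated) release. Provides product-limit estimation, LOESS
    smoothing with automated span selection by corrected AIC, probabilistic
    (seeded multiplicative noise with monotonicity repair) and deterministic
    (k-nearest-neighbour centroid) anonymisation, censoring-marker
    suppression, minimum-count disclosure guards, an in-process federation
    simulator, and a leave-one-out / ablation privacy-evaluation harness,
    together with a synthetic right-censored data generator for testing.
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
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
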