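Package: sptcca
Title: Cost-Consequence Modelling of Computer-Vision-Based Skin Prick Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Early cost-consequence model comparing computer-vision-assisted
    skin prick tests (SPTs) against the fully manual technique from a hospital
    perspective. Provides parameter construction from positive-count/sample-size
    pairs (Beta) and cost means with method-of-moments Gamma specifications,
    a two-arm diagnostic decision tree with expected-value rollback and
    incremental cost, one-way deterministic sensitivity analysis with tornado
    ordering, Monte Carlo probabilistic sensitivity analysis with convergence
    diagnostics, and an independent patient-level microsimulation oracle for
    validating the analytic rollback.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    rlang,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
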