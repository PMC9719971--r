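Package: abxsc
Title: Antibiotic-Cessation Outcome Estimation with Recurrent Embeddings and Synthetic Controls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates intensive-care patients' length-of-stay and mortality
    outcomes under the alternative scenarios of stopping versus continuing
    antibiotic treatment on any given day of their stay. A supervised
    bi-directional LSTM sequence autoencoder (implemented in compiled code)
    produces per-day patient embeddings; an adapted synthetic-control
    procedure selects nearest donors from day- and treatment-status-
    partitioned pools, solves a ridge weighting problem, and returns
    counterfactual outcome estimates evaluated through a control/impact-day
    framework. Includes a synthetic ICU cohort simulator with known,
    queryable counterfactual ground truth so the full pipeline is testable
    without credentialed EHR data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    arrow
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
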