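Package: effortirt
Title: Person Ability Estimation Under Rapid and Effortful Responding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Scoring toolkit for binary test items that corrects person
    ability (theta) estimates for rapid, non-effortful responding.
    Implements 2PL and 3PL logistic response models, ability-based
    guessing models, and effort-moderated mixtures in which responses
    flagged as rapid follow a constant guessing rate; flags rapid
    responses from item-level response-time percentiles and summarises
    them as a response-time-effort index; estimates theta by
    Newton-Raphson maximum likelihood or Bayesian modal estimation with
    standard errors from the test information function; and applies
    random-guessing and ability-based corrections to flagged rapid
    responders. A synthetic-data generator (engaged 2PL responding plus
    a lognormal rapid-guessing response-time mixture) supports
    parameter-recovery experiments, and a command-line interface scores
    CSV response matrices in batch.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
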