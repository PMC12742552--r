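Package: doseborrow
Title: Similarity-Informed Borrowing for Bayesian Dose-Finding Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage workflow for informing the degree of historical
    borrowing in model-based dose-finding trials. Estimates the similarity of
    source- and target-population dose-toxicity curves across multiple
    historical compounds with an ExNex (exchangeable/non-exchangeable) mixture
    model or a hierarchical intraclass-correlation model, translates the
    estimated similarity into robust-mixture prior weights or variance
    inflation factors for a two-parameter Bayesian logistic regression model
    (BLRM), and simulates continual-reassessment-method trials to quantify
    maximum-tolerated-dose selection accuracy under each borrowing strategy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    rjags,
    coda,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
SystemRequirements: JAGS (>= 4.0)
Config/testthat/edition: 3
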