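Package: phase2est
Title: Exact Design and Estimation for Two-Stage Phase II Trials with a
    Binary Endpoint
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Exact machinery for single-arm two-stage binomial trials with
    early stopping for futility and (optionally) efficacy. Maps terminal
    (stage, responses) outcomes onto a single ordered statistic under the
    stage-wise (Fairbanks-Madsen) ordering, computes its exact distribution
    and p-value function, and provides five point estimators of the response
    probability: the maximum likelihood estimator, a bias-corrected MLE, the
    uniformly minimum-variance unbiased estimator, its conditionally unbiased
    counterpart, and a median unbiased estimate, together with exact
    confidence bounds. Exact operating characteristics (type I error, power,
    expected sample size) and exact estimator bias and mean squared error --
    unconditional, conditional on reaching stage two, or averaged over a
    uniform prior -- support a search for admissible pairings of design and
    estimator that trade expected sample size against estimator performance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    Rcpp,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
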