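Package: adaptref
Title: Adaptive Individualised Reference Ranges for Longitudinal Biomarker Monitoring
Version: 0.1.0
Authors@R:
    person("adaptref", "developers", email = "adaptref@example.org", role = c("aut", "cre"))
Description: Static (tolerance-interval) and adaptive, individualised reference
    ranges for longitudinally monitored biomarkers. Implements a fully Bayesian
    hierarchical normal model with subject-specific within-subject variances,
    fitted by Gibbs sampling, and a fast streaming approximation based on the
    EM algorithm (SEMA) that maintains only a few sufficient statistics per
    subject. Includes individual-history and population-informed Z-score
    baselines, a leave-one-subject-out simulation framework that evaluates the
    abnormality-detection performance (ROC AUC) of the competing methods, and a
    command-line interface for batch and streaming use.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    coda,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
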