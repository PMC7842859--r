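Package: fedcohort
Title: Federated Learning of Multi-Hospital Clinical Risk Models on Simulated EHR Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates multi-hospital electronic-health-record cohorts with
    site-varying case mix and outcome prevalence, and compares three training
    strategies for 7-day mortality prediction: models trained locally at each
    site, a pooled model on combined data, and a federated model that
    exchanges only parameters with a central aggregator using sample-weighted
    federated averaging (FedAvg), optionally with Gaussian parameter noise.
    Includes L1-penalized logistic regression and multilayer perceptron
    classifiers trained by gradient descent with a shared parameter container,
    interhospital cohort comparison tables (chi-square, Kruskal-Wallis,
    Bonferroni adjustment, small-cell suppression), stratified Monte-Carlo
    cross-validation with bootstrap AUROC confidence intervals, and a
    config-driven experiment driver.
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
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    glmnet,
    withr,
    optparse
Config/testthat/edition: 3
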