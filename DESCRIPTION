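Package: asyncfed
Title: Asynchronous Staleness-Aware Federated Learning Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A deterministic, seedable single-process simulator for
    asynchronous federated optimization with per-parameter staleness
    weighting, a Bernoulli push gate, and Gaussian randomization of model
    updates for privacy, alongside a synchronous federated averaging
    (FedAvg) baseline and centralized SGD. Includes a hand-rolled text-CNN
    sentence classifier with three embedding fine-tuning modes, a convex
    logistic stand-in model, generators for labeled user-post corpora and
    Gaussian vector datasets with IID, pathological non-IID shard, and
    size-imbalanced partitioning, and confusion-matrix evaluation with
    convergence and communication-cost summaries.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
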