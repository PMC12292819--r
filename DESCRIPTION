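Package: otusynth
Title: Synthetic Augmentation and Explainable Classification of Microbiome OTU Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for balancing and augmenting sparse microbial count
    (OTU) tables with a Gaussian-copula synthesizer using kernel-density
    marginals, quality-gating the synthetic samples with adversarial
    real-versus-synthetic classification and a Kolmogorov-Smirnov test
    battery, ranking taxa with layer-wise relevance propagation (the
    epsilon rule) on a small dense network trained under cross-validation,
    ordinating samples by Bray-Curtis dissimilarity and principal
    coordinate analysis, and evaluating classifiers with Shapley
    attributions. Designed around the two-condition (adenomatous polyp
    versus colorectal cancer), three-specimen (stool, biopsy, saliva)
    study layout, with a seeded fixture generator so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    e1071,
    xgboost,
    randomForest,
    pROC,
    vegan,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr
Config/testthat/edition: 3
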