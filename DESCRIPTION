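Package: metastab
Title: Stability-Consensus Feature Selection and Prediction for Untargeted
    Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predictive-biomarker discovery workflow for case-control
    untargeted metabolomics feature tables. Provides redundancy
    (Pearson correlation) and dependency (mutual information) filters,
    ten feature-ranking routes built on random forests, linear
    support-vector machines with recursive feature elimination, and
    one-way ANOVA, a stability-consensus stage that combines the
    top-ranked sets into a formal context, enumerates its concept
    lattice (NextClosure), and selects features shared by a minimum
    number of techniques, plus three prediction pipelines (nested
    random-forest subsets, backwards variable elimination, logistic
    regression with collinearity pruning and stepwise AIC) and
    interpretation tools (empirical ROC/AUC with DeLong intervals,
    Welch t-tests, Pearson correlation networks, Apriori association
    rules on discretized intensities). A synthetic-data generator
    emulates the block-correlated structure of serum LC-MS feature
    tables so the whole pipeline is testable without cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    e1071,
    pROC,
    igraph
Suggests:
    testthat (>= 3.0.0),
    caret,
    withr,
    jsonlite
Config/testthat/edition: 3
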