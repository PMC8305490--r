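Package: ksrf
Title: Knowledge-Slanted Random Forests for Network-Guided Gene Expression Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene prioritization by random walk with restart over a weighted
    protein-protein interaction network, and a random-forest classifier whose
    per-node candidate split variables are sampled in proportion to the
    resulting per-gene probabilities. Uniform weights recover the conventional
    random forest. Provides the accompanying small-cohort evaluation protocol
    (leave-one-out cross-validation with per-class sensitivity, specificity
    and one-vs-rest AUC, ntree/mtry parameter sweeps, per-gene one-way ANOVA,
    gene selection-frequency ranking), readers and writers for STRING-style
    edge lists and expression/label tables, a synthetic-study simulator with
    planted network structure, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    ranger,
    optparse
Config/testthat/edition: 3
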