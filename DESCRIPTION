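Package: refsig
Title: Recursive Ensemble Feature Selection for Microbiome Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and cross-cohort validation of microbiome biomarker
    signatures from 16S rRNA amplicon sequence variant (ASV) count tables.
    Implements recursive ensemble feature selection (REFS): an ensemble of
    eight classifiers ranks features under stratified ten-fold
    cross-validation, the least important 20% of ASVs are removed each
    cycle until one remains, and the best-performing cycle of the best of
    several replicate runs defines the signature. A held-out panel of five
    further classifiers evaluates the signature by cross-validated ROC AUC.
    Signatures transfer to independent cohorts sequenced with longer reads
    by exact subsequence matching of ASV sequences, with abundances of all
    containing ASVs aggregated. Includes a Dirichlet-multinomial simulator
    of paired case-control cohorts with planted discriminative ASVs and
    engineered sequence containment, standardized differential-abundance
    summaries, and heat-map export.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    glmnet,
    jsonlite,
    nnet,
    pheatmap,
    ranger,
    rpart,
    stats,
    tools,
    utils,
    xgboost
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
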