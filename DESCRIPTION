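Package: methgen
Title: Conditional Generative Simulation of DNA Methylation Beta Values
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates Illumina 450K-style DNA methylation beta-value
    matrices for a user-specified condition (e.g. cancer type). The core
    generator is a conditional variational autoencoder trained per chunk of
    CpG sites on (beta value, condition) pairs and sampled from a standard
    normal latent prior; a per-(CpG, condition) beta-distribution generator
    fitted by the method of moments serves as a benchmark. Includes a
    four-step missing-value preprocessing pipeline (all-missing CpG removal,
    CpG chunking, IQR-based outlier sample removal, median imputation), a
    ground-truth synthetic data generator for testing, and a classifier-based
    evaluation protocol (decision tree, naive Bayes, random forest, k-nearest
    neighbours, support vector machine; accuracy, one-vs-rest AUC, confusion
    matrices) that checks whether generated samples are recognized as their
    intended condition.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    randomForest,
    rpart,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
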