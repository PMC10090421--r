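Package: acpGBDT
Title: Anticancer Peptide Classification from Sequence Descriptors with
    Gradient Boosted Trees
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classifies peptides as anticancer (ACP) or non-anticancer from
    primary sequence alone. Peptides are encoded with a merged descriptor:
    the 188-dimensional SVM-Prot style vector (20 amino-acid composition
    frequencies plus composition/transition/distribution summaries over
    eight physicochemical groupings) concatenated with per-residue AAindex
    physicochemical values of the first ten and last ten residues. A
    gradient boosted decision tree is trained on the merged features and
    evaluated by stratified ten-fold cross-validation and independent
    testing with sensitivity, specificity, accuracy, Matthews correlation
    and ROC AUC. Includes a synthetic peptide generator with class-
    conditional composition bias for offline testing, and a harness that
    runs alternative classifiers through the same interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    BiocGenerics,
    xgboost,
    randomForest,
    rpart,
    e1071,
    class,
    glmnet,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Classification, Proteomics, FeatureExtraction, MachineLearning
RoxygenNote: 7.3.3
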