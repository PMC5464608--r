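Package: icapr
Title: Indicator-Cell Assay Classification of Serum-Induced Transcriptional Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building blood-based disease classifiers from the
    transcriptional response of standardized indicator cells exposed to serum or
    plasma. Implements the full analysis chain: exon-to-gene summarization,
    array quality control by Grubbs screening of average inter-array
    correlations, batch normalization through a marker-gene linear model,
    gene-set scoring with the maxmean statistic and permutation
    restandardization, shadow-feature family-wise error rate ranking against
    random-forest or fern importances, nested polynomial-kernel SVM voting
    ensembles, minimum-entropy active learning for blinded test sets, and the
    evaluation statistics (exact binomial tails, Matthews correlation
    significance, vote-threshold ROC curves, cross-validation harnesses with
    in-fold feature selection). A seeded synthetic-cohort generator with
    planted differential gene sets, batch effects coupled to marker genes and
    off-signature disease cohorts makes every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    randomForest,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
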