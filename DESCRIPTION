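Package: acpforest
Title: Physicochemical Consensus Feature Selection and Random-Forest
    Classification of Anticancer Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Encodes peptide sequences as amino-acid physicochemical
    feature vectors by AAindex1 lookup and average pooling, ranks features
    with four filter/embedded selectors (ANOVA F, chi-squared, mutual
    information, histogram gradient boosting), applies a two-round
    cross-dataset consensus intersection to obtain a compact feature set,
    and trains random-forest classifiers evaluated with Sn/Sp/ACC/MCC/AUC,
    Gini importance and out-of-bag permutation importance. Includes a
    synthetic benchmark generator with planted class signal for
    end-to-end validation, and a FASTA-in prediction interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ranger,
    xgboost,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    randomForest
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
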