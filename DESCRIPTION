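Package: procleave
Title: Protease Substrate Cleavage-Site Prediction from Peptide Window
    Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for training and applying protease-specific substrate
    cleavage-site predictors. Extracts P8-P8' peptide windows around candidate
    scissile bonds, encodes them with eleven sequence, evolutionary,
    physicochemical and structural feature schemes (up to 4562 components),
    selects features with a two-step minimum-redundancy-maximum-relevance plus
    forward-selection procedure, trains support vector regression models with
    cross-validated grid search, and scans full-length protein sequences to
    rank candidate cleavage sites at a chosen specificity level. A synthetic
    substrate generator with planted position-weight-matrix cleavage motifs
    lets the full pipeline run and be tested without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
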