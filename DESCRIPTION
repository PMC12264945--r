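Package: attnprobe
Title: Probing Transformer Attention Maps for Molecular Contact Structure
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for asking whether the self-attention maps of sequence
    language models encode molecular structure. Builds binary residue contact
    maps from 3D coordinates (distance cutoff) or dot-bracket secondary
    structure (including pseudoknot tiers), quantifies per-head agreement
    between attention weights and contacts with and without a confidence
    threshold, refines attention maps by symmetrization and average product
    correction, extracts balanced token-pair feature tables, trains lightweight
    classifiers (logistic regression, decision tree, random forest, multilayer
    perceptron, gradient boosting, and a small native convolutional network) to
    predict contact maps, and scores predictions with macro-F1 and the Matthews
    correlation coefficient. A synthetic-data module plants tunable structural
    signal into simulated attention stacks so the whole pipeline can be
    exercised and validated without any pretrained language model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    ranger,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    xgboost
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
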