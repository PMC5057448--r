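Package: hlrdecode
Title: Hierarchical Logistic Regression Decoding of Semantic Categories from fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decodes the presence of object and action categories, organized in a
    WordNet-style hypernym taxonomy, from multivoxel BOLD fMRI time series.
    Implements hierarchical logistic regression (HLR): one conditional logistic
    model per category, trained only on time points where all of the category's
    hypernyms are present, with marginal category probabilities obtained as
    products of conditionals along the ancestor closure. Includes BOLD
    preprocessing (median-filter detrending, z-scoring, repeat averaging, lagged
    feature construction), encoding-model-based voxel selection, gradient-descent
    fitting with early stopping, L2-penalized and label-noise-robust variants,
    beta-prior output smoothing, and the full evaluation suite: per-category
    ROC/AUC against block-shuffle permutation nulls with a symmetric beta fit and
    Benjamini-Hochberg FDR control, conditional AUC with per-edge taxonomy
    consistency testing, and per-timepoint log likelihood ratios. A synthetic-data
    generator produces hierarchy-closed label streams and category-tuned lagged
    BOLD responses so the whole pipeline is testable without any recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    generics
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    optparse,
    withr
Config/testthat/edition: 3
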