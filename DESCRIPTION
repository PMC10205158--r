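Package: lexrsa
Title: Searchlight Representational Similarity Analysis of Lexical Similarity Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds word-pair similarity models from affective ratings, word
    embeddings, phonological transcriptions and taxonomies, and relates them to
    fMRI activity patterns through a whole-brain searchlight representational
    similarity analysis (RSA). Includes trial-wise BOLD area-under-the-curve
    activation extraction with motion quality control, plain and partial
    Spearman searchlight RSA, group-level inference with permutation
    cluster-extent familywise-error control, dependent-correlation model
    comparison (Pearson-Filon), and a synthetic-data generator that plants
    known representational geometry for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr,
    RNifti,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
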