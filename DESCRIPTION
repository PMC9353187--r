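Package: methtransfer
Title: Completing Sparse WGBS Methylomes by Multi-Task Transfer Learning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Imputes missing CpG methylation states in extremely sparse
    whole-genome bisulfite sequencing (WGBS) profiles, such as those of
    oocytes and preimplantation embryos. A multi-task neural network
    combines a convolutional subnetwork over a one-hot DNA sequence window
    with a bidirectional gated-recurrent-unit subnetwork over neighboring
    CpG methylation levels, trained with a Kullback-Leibler divergence
    objective on continuous methylation levels. Pretrained subnetworks
    from dense source methylomes can be transferred (frozen or fine-tuned)
    into models for sparse target profiles. Includes call-file parsing and
    cleaning (depth, single-strand and hemi-methylation filters),
    confidence-thresholded imputation, genomic-feature coverage
    summaries, and a synthetic multi-profile methylome generator for
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    jsonlite,
    generics,
    ggplot2,
    pROC,
    Biostrings,
    IRanges,
    S4Vectors,
    BiocGenerics,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
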