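Package: sarcomix
Title: Radiomic and Transcriptomic Subtyping of Soft-Tissue Sarcoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully synthetic-testable pipeline for multi-omic
    prognostication of locally advanced soft-tissue sarcoma from baseline MRI
    and bulk RNA-seq. Covers MRI intensity harmonization (resampling, bias-field
    correction, histogram matching, gray-level discretization), handcrafted
    texture and shape radiomics with an intraclass-correlation reproducibility
    filter, convolutional-autoencoder deep radiomics with an optional
    prognostic (Cox) loss, resampling-based consensus clustering with centroid
    assignment, survival statistics (Kaplan-Meier, log-rank, Cox regression,
    backward-AIC selection, cross-validated Harrell concordance with bootstrap
    comparison), and transcriptomics (batch correction, voom normalization,
    differential expression, over-representation enrichment, nearest-shrunken-
    centroid signatures). A synthetic cohort generator with planted imaging
    phenotypes, survival structure, and differential genes makes every stage
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    limma,
    sva,
    RNifti,
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
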