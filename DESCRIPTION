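Package: adtd
Title: Adaptive Digital Tissue Deconvolution of Bulk Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates cell-type proportions from bulk gene-expression profiles
    together with a hidden background profile and its per-sample weight, while
    adaptively rescaling cell-type reference profiles to reveal cell-type-specific
    gene regulation. Implements loss-function learning of per-gene weights from
    training mixtures of known composition, a block-coordinate solver for the
    constrained quadratic programs of the adaptive deconvolution model, a
    pseudo-bulk mixture simulator with hidden cell populations and spiked
    regulation for validation, and evaluation metrics (per-cell-type Pearson
    correlation, hidden-contribution recovery, regulation-detection AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    pROC
Config/testthat/edition: 3
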