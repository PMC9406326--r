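Package: cvfair
Title: Fair Comparison of Complex-Valued and Real-Valued Convolutional
    Networks for Disease Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Paired complex-valued and real-valued convolutional neural
    networks for two-class biomedical image classification (dermoscopy
    lesions, heart-sound scalograms), built from first principles: a
    complex layer algebra (complex convolution, zReLU, average pooling,
    complex dense layers) carried as paired real tensors, Fourier-domain
    input conversion through the DFT Vandermonde matrix with Hermitian
    reduction, parameter-matched paired architectures, stratified 10-fold
    cross-validated training with a complex-adapted Adam optimiser, and a
    normality-gated statistical comparison (Shapiro-Wilk gate, Welch t or
    Mann-Whitney U) with ROC-space distance summaries. Ships synthetic
    two-class image generators and the published per-fold metric tables
    so the full pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    jsonlite,
    png,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
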