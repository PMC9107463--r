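Package: clockvae
Title: Two-Latent Variational Autoencoder Analysis of Clock Drawing Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-supervised analysis of clock drawing test (CDT) images for
    dementia screening. Provides a procedural generator of synthetic clock
    drawings with known generative factors, a contour-crop/size-filter/resize
    preprocessing chain producing 10,000-element flattened rasters, a
    two-latent variational autoencoder (10,000-512-2) trained with a binary
    cross-entropy reconstruction loss and Gaussian-prior KL term, latent-space
    traversal and factor-correlation analysis, encoder fine-tuning for
    dementia/control classification, a k-nearest-neighbour operationalization
    of the latent plane, and bootstrap confidence intervals for the usual
    classifier metrics (AUROC, AUPRC, accuracy, F1, precision, sensitivity,
    specificity, NPV).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
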