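Package: v1sparse
Title: Sparse Coding Models of V1 with Non-Convex Thresholding Operators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sparse-coding generative models of primary visual cortex (V1)
    learned from whitened natural-image patches. Implements alternating
    proximal-gradient coding and dictionary learning under four
    sparsity-promoting penalties (l1/soft thresholding, l1/2 half
    thresholding, l0 hard thresholding, and the CEL0 continuous exact l0
    relaxation), the Olshausen-Field style image preprocessing pipeline
    (whitening, variance rescaling, patch extraction), synthetic data
    generators (1/f pink-noise images and planted k-sparse linear models),
    and a receptive-field analysis suite (grating-bank orientation tuning,
    circular variance, Gabor-shape fitting) for comparing the regularizers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    minpack.lm,
    png
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
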