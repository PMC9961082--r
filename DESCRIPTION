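Package: sportnir
Title: Sequential Orthogonalized Multi-Block PLS Calibration for NIR Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Multivariate calibration toolkit for quantifying an active
    pharmaceutical ingredient in powder mixtures from near-infrared spectra.
    Implements single-block partial least squares (NIPALS PLS1) with variable
    importance in projection (VIP), and SPORT - sequential preprocessing
    through orthogonalization - which fuses differently preprocessed copies
    of one spectral block by sequentially orthogonalized PLS sub-models.
    Includes standard normal variate and Savitzky-Golay derivative
    pretreatments, concentration-ranked train/test splitting, sample-grouped
    k-fold cross-validation with an exhaustive latent-variable grid search,
    a Gaussian-band NIR mixture simulator, and readers/writers for delimited
    spectra matrices and JCAMP-DX.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
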