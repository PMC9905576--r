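Package: pinncal
Title: Unsupervised Physics-Informed Neural Network Calibration of Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Extracts analyte concentrations from emission spectra contaminated
    by non-stationary background and noise, without labelled calibration data.
    A one-dimensional convolutional autoencoder predicts the background
    spectrum of each measurement; after background subtraction a small
    convolutional head predicts the concentrations. The whole network is
    trained unsupervised by minimising a physics-informed loss: the squared
    mismatch between the measurement and the sum of the predicted background
    and the concentration-scaled reference spectra, plus a first-derivative
    smoothness penalty on the predicted background. Includes seeded generators
    for six synthetic benchmark families (Gaussian two-peak references with
    constant, shaped, and randomly varying backgrounds plus Gaussian noise),
    a per-spectrum least-squares baseline, evaluation metrics, and plain-text
    spectrum and dataset input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
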