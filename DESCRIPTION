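Package: paox
Title: Wavelength-Flexible Data-Driven Photoacoustic Oximetry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimation of blood oxygen saturation (sO2) from multispectral
    photoacoustic amplitude spectra on a 700-900 nm grid. Implements a
    wavelength-masked recurrent (LSTM) regressor that accepts spectra with
    arbitrary missing wavelengths, together with linear-unmixing and learned
    spectral decoloring baselines; a fast analytic layered-tissue simulator
    that generates spectrally colored training spectra for a family of tissue
    variants; the spectra selection, z-score normalisation and stratified
    resampling pipeline; and a per-wavelength Jensen-Shannon distance between
    datasets that predicts which training distribution best matches a target
    dataset. Includes reproducible experiment drivers for wavelength sweeps,
    cross-validation matrices and divergence-versus-error studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    data.table,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
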