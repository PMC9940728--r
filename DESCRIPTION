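Package: phantomkit
Title: Design of Multipigment Tissue-Simulating Optical Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing solid tissue-simulating optical phantoms from
    mixtures of absorbing and scattering pigments. Given per-concentration
    pigment optical-property bases and a target tissue described by its
    absorption and reduced-scattering spectra, a measured diffuse-reflectance
    spectrum, or a chromophore composition, the package computes the
    nonnegative pigment recipe that best matches the target over 370-950 nm.
    Includes weighted and band-restricted nonnegative least-squares property
    fitting, a white Monte Carlo photon-transport forward model for diffuse
    reflectance with nonlinear recipe inversion, a Mie-Rayleigh scattering
    power-law model, a computational skin absorption model with three-band
    inversion to hemoglobin oxygen saturation, blood volume and melanosome
    fractions, and spectral similarity metrics (mean absolute error and the
    spectral angle mapper).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    pracma,
    minpack.lm,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
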