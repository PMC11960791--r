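Package: lungoptics
Title: Lung Tissue Optical Properties and Light Dosimetry for Photodynamic Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising the optical properties of peripheral lung
    tissue and for simulating therapeutic light delivery during interstitial
    photodynamic therapy (PDT). Implements a layered-slab Monte Carlo forward
    model of double-integrating-sphere measurements, inverse Monte Carlo
    extraction of absorption and reduced scattering spectra from diffuse
    reflectance and total transmittance, decomposition of absorption spectra
    into water, oxy-/deoxyhemoglobin and dry-tissue contributions (blood
    volume fraction and oxygen saturation estimation), voxel-based Monte
    Carlo photon transport from a cylindrical side-firing diffuser in a
    three-dimensional lung phantom, and reduction of the resulting fluence
    and energy-deposition fields to cumulative volume histograms and
    threshold-coverage metrics. A synthetic-data generator reproduces the
    statistical structure of ex vivo lung spectra so the whole pipeline is
    testable without measured data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
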