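Package: wavepsf
Title: Point Spread Function Estimation from Computed Wavefronts for
    Hyperspectral Image Deconvolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates spatially and spectrally varying point spread
    functions (PSFs) of hyperspectral imaging systems from computed
    wavefronts. Wavefronts are parameterized by Zernike polynomial
    coefficients and optimized by simulated annealing so that
    Richardson-Lucy deconvolution of an image patch best matches a
    ground-truth template under the normalized cross-correlation metric.
    Coefficients estimated at a small set of key patches and key
    wavelengths are interpolated with low-order polynomials across the
    field of view and the spectral axis, yielding a noise-free, smoothly
    varying PSF field used for patchwise deconvolution of full
    hyperspectral cubes. Includes ENVI cube input/output, a synthetic
    push-broom scene generator for validation, and vegetation-index
    utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    graphics,
    grDevices,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
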