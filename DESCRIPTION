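Package: ipws
Title: Interference-Based Imaging of Nanoscale Structure and Macromolecular Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for dual partial wave spectroscopy (PWS)
    microscopy, in which light backscattered from sub-diffraction
    refractive-index fluctuations interferes with a strong substrate
    reflection. From spectral image cubes I(lambda, x, y) the package computes
    nanoscale-structure maps (Sigma_s); from temporal cubes I(t, x, y) it
    computes fluctuation-variance maps (Sigma_t^2), fractional moving mass
    (m_f), and diffusion coefficients (D) via the temporal autocorrelation of
    the interference signal, with empty-field reference-noise subtraction and
    finite-exposure correction. It detects per-pixel bursts of motion
    (cellular paroxysms) at single-frame resolution with changepoint
    statistics, and includes a first-principles nanosphere-phantom simulator
    (Brownian dynamics plus a scalar interference forward model with shot
    noise, read noise and LED drift) that provides Stokes-Einstein ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    purrr,
    tidyr,
    ggplot2,
    generics,
    tiff,
    yaml,
    jsonlite,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
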