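Package: smlmpsf
Title: Multidimensional Information from Unmodified Single-Molecule PSFs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extracting fluorophore color and axial (z) position
    from the unmodified point spread function (PSF) of single emitters in
    localization microscopy. Includes a Gibson-Lanni stratified-medium PSF
    simulator with Poisson shot noise, tricubic-spline PSF models with
    Poisson maximum-likelihood fitting and Cramer-Rao lower bounds,
    fully-connected neural networks for color classification (with
    confidence-based rejection) and axial regression, the 13x13-patch
    preprocessing pathway shared by both networks, and an end-to-end
    inference and evaluation pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    pracma,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
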