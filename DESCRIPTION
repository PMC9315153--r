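Package: muellerscope
Title: Resolution Effects in Mueller Matrix Microscopy of Fibrous Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how objective numerical aperture and magnification
    shape the polarization properties derived from transmission Mueller matrix
    microscopy of fibrous (collagen-like) media. Implements a forward model of
    the dual-rotating quarter-wave-plate polarimeter and Mueller matrix
    reconstruction from intensity traces, the Lu-Chipman polar decomposition
    into diattenuation, linear retardance and depolarization images,
    first-order moments and gray-level co-occurrence (Haralick) texture
    features, exact light scattering by infinite circular cylinders with the
    derived phase functions, a polarized photon Monte Carlo through slabs of
    oriented cylinders with angle-resolved transmission Mueller matrices, a
    seeded synthetic fibrous-tissue generator with an NA-dependent imaging
    degradation model, and a study pipeline producing tidy texture tables and
    cross-magnification Pearson correlation analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    EBImage,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
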