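Package: spinefield
Title: Volume-Conductor Modelling of Trans-Spinal Direct Current Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a parametric multi-tissue torso and spine voxel model,
    assigns isotropic and volume-constrained anisotropic tissue conductivity
    tensors, solves the quasi-static current-flow (Laplace) problem for
    skin-mounted electrode montages with a conservative finite-volume
    discretization, and analyses the induced electric field in the spinal
    cord: slice-averaged magnitude and directional components along the
    cord, per-spinal-segment maxima, suprathreshold regions, dorsal root
    ganglion probes, session dosimetry, and montage comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    Rcpp,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
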