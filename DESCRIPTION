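Package: holofield
Title: Physics-Guided Neural-Field Phase and Absorbance Retrieval for
    In-Line X-Ray Holography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Single-shot retrieval of phase and absorbance maps from
    shot-noise-limited in-line X-ray holograms.  Provides an angular
    spectrum method (ASM) optics core with a multi-slice forward model,
    a synthetic phantom and Poisson shot-noise hologram simulator, object
    mask labelling from the in-focus hologram, a coordinate-based neural
    field with Fourier-feature positional encoding trained against the
    physical forward model, Gerchberg-Saxton and residual U-Net baselines,
    and region-wise evaluation metrics (means, MAE, SSIM, percentage
    errors).  All gradients are computed analytically in-package,
    including reverse-mode differentiation through the FFT-based wave
    propagation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
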