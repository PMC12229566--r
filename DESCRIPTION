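Package: parvomagno
Title: Developmentally Staged Training and Receptive-Field Analysis for
    Convolutional Models of the Parvo/Magno Distinction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how a developmentally staged ("biomimetic")
    progression of training inputs - from blurred, achromatic images to
    sharp, full-colour ones - shapes the first-layer receptive fields and
    decision biases of a small convolutional image classifier. Provides a
    synthetic image/video generator with separable global-shape and
    local-texture cues, declarative training regimens, a compact 2D/3D
    convolutional network trained with SGD and Nesterov momentum,
    spectral receptive-field metrics (amplitude-weighted mean spatial
    frequency, orientation mean resultant length, colour-channel
    discrepancy, temporal variation), shape-versus-texture cue-conflict
    bias evaluation, rank-based unit ablation curves, and layer-wise
    activation-invariance analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    grDevices,
    tibble,
    tidyr,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
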