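Package: usnlm
Title: Non-Local Means Speckle Reduction and Quality Control for B-Mode
    Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Reduces speckle noise in B-mode ultrasound images with a
    non-local means (NLM) denoiser and benchmarks it against classical
    median and adaptive Wiener filters using the two standard
    quality-control statistics, contrast-to-noise ratio (CNR) and
    coefficient of variation (COV).  Includes a seeded generator of
    synthetic gray-scale phantoms (six graded circular targets in the
    style of an ATS-539 multipurpose phantom) and of a thyroid-like
    scene, corrupted by Rayleigh-distributed multiplicative speckle, so
    the whole denoiser comparison can be reproduced without acquired
    scans.  Results are tidy tibbles with broom-style tidy() and
    glance() methods and ggplot2 autoplot() figures; a small command
    line front end ties simulation, denoising and evaluation together.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
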