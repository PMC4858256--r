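Package: onhperf
Title: Optic Nerve Head Perfusion Quantification from OCT Angiography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and quantification pipeline for optic nerve head
    (ONH) perfusion imaging with optical microangiography (OMAG), an OCT
    angiography technique. Generates synthetic repeated-B-scan complex OCT
    volumes with known ground truth, computes the inter-B-scan decorrelation
    flow signal, isolates the pre-laminar tissue slab by gradient-based
    layer segmentation and Bruch's membrane disc-margin delineation,
    projects en-face angiograms, detects vessels with a multiscale Hessian
    (Frangi-type) vesselness filter, and derives three perfusion metrics
    (flux, vessel area density, normalized flux). A companion statistics
    stage simulates per-eye clinical cohorts and reproduces the study-style
    analyses: mean ocular perfusion pressure, two-sample power and sample
    size, one-way ANOVA, t-tests and univariate regressions with tidy
    outputs.
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
    jsonlite,
    readr,
    MASS,
    mgcv
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
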