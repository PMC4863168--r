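Package: sptmotion
Title: Motion-Mode Classification for Single-Particle Tracking Trajectories
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for two-dimensional single-particle tracking
    of intracellular vesicles, such as lipoplex-loaded endosomes imaged by
    time-lapse confocal microscopy. Computes time-averaged mean square
    displacement (MSD) curves and fits Brownian (4*D*tau + offset) and
    flow (4*D*tau + (v*tau)^2 + offset) motion models; quantifies
    trajectory shape through the gyration tensor and its asphericity;
    calibrates asphericity thresholds by Monte-Carlo simulation of pure
    Brownian walks; segments trajectories into alternating diffusion and
    flow-motion domains with a speed-plus-local-asphericity rule; and
    summarises diffusion/flow population fractions over track ensembles.
    Includes a synthetic-trajectory generator with known ground truth,
    object-based and pixel-based (Manders M1) colocalization statistics,
    and Stokes-Einstein / Smoluchowski unit conversions.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
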