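Package: prehensr
Title: Reach-to-Grasp Kinematics and Grasp-Placement Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing three-dimensional motion-capture recordings of
    seated reach-to-grasp movements. Provides marker-trajectory input/output
    (tab-separated exports and standard C3D), gap filling, velocity-threshold
    movement segmentation, temporal features (peak velocity, adjustment time),
    grip-aperture features (maximum grip aperture and its timing), conical
    frustum centre-of-mass computation, signed grip-deviation scoring, a
    synthetic trial generator with known ground truth, and the accompanying
    statistical battery: repeated-measures ANOVA with generalized eta squared,
    random-intercept linear mixed models with likelihood-ratio term tests,
    Kruskal-Wallis tests, and a native cumulative-link mixed model for ordinal
    ratings fitted by adaptive Gauss-Hermite quadrature.
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
    lme4,
    MASS,
    numDeriv,
    purrr,
    readr,
    rlang,
    signal,
    statmod,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    broom,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
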