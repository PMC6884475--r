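Package: sonolane
Title: Closed-Loop Simulation of Auditory Sensory Substitution for Lane Keeping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A reproducible simulation pipeline for studying auditory sensory
    substitution of vehicle lateral position during lane keeping. Provides a
    procedural generator for winding road courses, a constant-speed kinematic
    vehicle model, a binaural white-noise encoder that maps lateral deviation
    to per-ear sound levels, synthetic driver agents implementing a two-level
    (anticipatory/compensatory) steering controller under three sensory
    conditions (normal vision, visual occlusion, occlusion plus auditory
    substitution), the two standard driving-performance metrics (standard
    deviation of lateral position and steering-wheel velocity during curve
    negotiation), and a mixed repeated-measures ANOVA analysis with
    Greenhouse-Geisser correction, simple main effects, and Shaffer's
    sequentially rejective multiple-comparison procedure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
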