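Package: combmetrics
Title: Geometric Measurement of Stimulus-Guided Honeycomb Construction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Landmark-based analysis pipeline for honeycomb construction
    experiments in which wax tabs carrying artificial stimuli (pressed pits,
    pit pairs, V-shaped strips, and hybrid forms) are offered to honeybee
    colonies and the geometry of the subsequently built cell walls is
    measured against the geometry the stimuli predict. Provides four-point
    projective (homography) registration of before/after photograph frames,
    four stimulus-to-wall metrics (pit rim angular overlap, divergence from
    the pit-pair common tangent, divergence from the V bisection, and the
    apex proximity ratio), randomized virtual-stimulus control populations,
    per-experiment statistical comparisons, and a seeded synthetic comb
    generator with known ground truth so the full pipeline can be exercised
    and calibrated without photographs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
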