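Package: wormtrackr
Title: Multi-Worm Video Tracking and Locomotion Metrics for C. elegans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segments multiple Caenorhabditis elegans from plate or liquid
    recordings, tracks individuals with collision censoring, and computes six
    physiological metrics: worm area, worm length, crawl speed, swim speed,
    dynamic amplitude, and wave initiation rate (thrashing). Worm bodies are
    reduced to midlines by binary thinning; signed Menger curvature at seven
    tracking points drives zero-crossing stroke counting. A synthetic
    serpenoid worm-video generator with full analytic ground truth
    (trajectories, arclengths, curvatures, collision and curl schedules)
    supports validation without any recorded footage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    png,
    tiff,
    rlang,
    parallel,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
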