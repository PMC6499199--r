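Package: tlsdyn
Title: Cluster-Based Monitoring of Structural Plant Dynamics from
    Terrestrial Laser Scanning Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify short-interval structural dynamics (such as
    circadian branch and leaf movement) of trees and other targets from
    terrestrial laser scanning (TLS) point-cloud time series. The pipeline
    reads and filters per-epoch point clouds, fits reference spheres and
    estimates sphere-based rigid co-registration, clusters a target once
    with Poisson-disk dart-throwing seeds and Euclidean nearest-seed
    labeling, propagates cluster labels through time by nearest-neighbor
    search, and summarises per-cluster 3D displacement in height-normalized
    cylindrical maps and percentile statistics. A parametric synthetic-scene
    generator (deforming tree, static lamppost, reference spheres) provides
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    tools,
    yaml,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
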