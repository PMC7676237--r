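Package: livsampler
Title: Autonomous Adaptive Sampling for Scanning Hyperspectral Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grid-less autonomous adaptive data acquisition for scanning
    hyperspectral (FTIR) microscopy. Implements the LIV sequential sampling
    strategy -- a surrogate model built by Delaunay barycentric linear
    interpolation whose per-point leave-one-out cross-validation errors are
    regularized by boundary-clipped Voronoi cell areas to decide where to
    measure next -- together with uniform-grid, uniform-random and
    largest-unexplored-region baselines, an IR preprocessing module
    (band restriction, rubber-band baseline correction, PCA), simulation
    benchmarks against ground-truth raster maps (Voronoi-weighted LOO error,
    ground-truth RMSE, on-target ratio), and seeded generators of synthetic
    two-component and worm-like spectral maps so the whole acquisition loop is
    testable without instrument hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble
LinkingTo: Rcpp
Suggests:
    deldir,
    interp,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
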