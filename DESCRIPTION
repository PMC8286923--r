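Package: fcnembed
Title: Embedded Functional Connectivity Networks from Independent Component
    Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds binary functional connectivity networks (FCN) from
    per-subject independent-component time courses by combining two
    time-series distance metrics (lag-maximised cross-correlation and
    Euclidean) with five manifold-learning embeddings (classical MDS,
    ISOMAP, diffusion maps, Gaussian kernel PCA and distance-based locally
    linear embedding), followed by proportional thresholding and three
    global graph measures (average path length, global clustering
    coefficient, median degree). Includes a RAICAR-style reproducibility
    ranking of repeated ICA realizations, a repeated stratified k-fold
    classification harness over the graph features, a full
    method-by-metric-by-threshold sweep, and a synthetic cohort generator
    so the whole pipeline can be exercised without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    graphics,
    igraph,
    jsonlite,
    nnet,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    kernlab,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
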