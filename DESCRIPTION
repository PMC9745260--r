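Package: RGUCkit
Title: Spatially Explicit Conservation Genetics for Dominant Markers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Conservation-genetics workflow for dominant (presence/absence)
    marker data such as AFLP bands. Selects Relevant Genetic Units for
    Conservation (RGUCs) from rare-band loss probabilities and R-value
    sampling theory, optimizes population contributions to a
    diversity-maximizing seed bank from average coancestries, estimates
    population structure (AMOVA Phi-ST, Mantel and spatial autocorrelation
    diagnostics, k-means cluster surrogate), and models genetic turnover
    along bioclimatic gradients with a per-locus classification-tree
    ensemble whose split importances are turned into cumulative genetic
    importance functions, projected and grouped over raster grids. Includes
    a synthetic-data generator emulating the statistical structure of a
    multi-population dominant-marker study so the full pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    vegan,
    cluster,
    rpart,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
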