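Package: crypsis
Title: Phylogenetic Analysis of Animal-Habitat Colour Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative analysis of camouflage through background colour
    matching. Quantifies specimen fur colouration from standardized photographs
    (white/black balance correction, patch means, BT.601 total reflectance) and
    habitat colouration from multi-band reflectance rasters (temporal averaging,
    point-buffer extraction). Estimates phylogenetic signal with phylogenetic
    eigenvector regression (PVR), Moran's I eigenvector selection and
    phylogenetic signal-representation (PSR) curves, and tests phenotype-habitat
    matching with multi-response partial least squares regression (NIPALS) under
    geographic and collection-origin covariates, with Q2 cross-validation,
    squared-weight variable importance and bootstrap coefficient inference. A
    synthetic-data generator reproduces the statistical structure of such a
    study (Brownian species effects on a Yule tree, habitat gradients, origin
    offsets) so the full pipeline can be exercised and validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    graphics,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
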