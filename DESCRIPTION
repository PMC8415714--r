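Package: fruitpore
Title: Pore Microstructure Analysis of X-Ray CT Fruit Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies the pore (intercellular air) space of fruit tissue
    from reconstructed X-ray micro-CT volumes. Provides fruit/air masking,
    histogram deep-valley phase segmentation, 3D pore labeling and
    morphometry (porosity, equivalent-sphere diameters, size histograms,
    axial porosity profiles), topology-preserving curve-skeleton
    pore-network extraction with throat and coordination statistics,
    mesocarp risk-zone partitioning with core shape analysis, and a
    synthetic fruit-phantom generator with exact ground truth for
    validating every stage. Includes volume I/O for multi-page TIFF, TIFF
    slice directories and MHD+raw.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    tiff,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
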