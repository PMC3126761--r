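Package: poremetry
Title: Pore-Size Metrology for TEM Micrographs of Fibrous Hydrogel Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the pore structure of fibril-network hydrogels (such
    as calcium-alginate microcapsules) from transmission electron micrographs.
    Implements a complete image-metrology pipeline: illumination-inhomogeneity
    correction, edge-preserving total-variation denoising,
    coherence-enhancing shock filtering, two-phase segmentation with a
    minimum-lumen-area filter, exact Euclidean distance transforms,
    medial-axis skeleton extraction, and skeleton-sampled relative pore radii
    and fibril radii with binned percent-frequency distributions.  Also
    provides depth-resolved pore statistics relative to a cell-contour mask,
    BET specific-surface-area and BJH pore-size-distribution analysis of
    nitrogen physisorption isotherms for cross-validation, and synthetic
    phantom generators with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
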