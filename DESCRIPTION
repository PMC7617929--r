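Package: rhizotrack
Title: Motility Tracking and Symbiosis Assay Analysis for Rhizobia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantifying Rhizobium leguminosarum motility
    and symbiosis phenotypes. Simulates run-and-tumble swimmers and renders
    them as capillary-microscopy frame stacks, detects and links bacterial
    spots into single-cell trajectories, and estimates per-track swimming
    speed and tumble rate. Also fits four-parameter log-logistic (or linear)
    models to swimming-halo dose-response data, gates flow-cytometry events
    into undifferentiated bacteria versus bacteroids, and counts stained
    nodules in root photographs by colour segmentation. Every stage is
    validated by parameter recovery against the synthetic generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    tiff,
    png,
    jsonlite,
    minpack.lm,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
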