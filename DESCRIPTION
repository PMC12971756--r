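Package: pollenscape
Title: Functional Landscape Connectivity Metrics for Pollinator-Mediated
    Gene Flow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Raster-based functional landscape connectivity metrics for
    pollinator-mediated gene flow, built on an incidence function model
    redefined over 10 m raster cells and extended with gap-crossing
    behaviour (unlimited, 50 m threshold, and probabilistic negative
    exponential modes). Includes pollen-pool response statistics inferred
    from maternal-offspring microsatellite genotypes (pollen haplotype
    subtraction, Nei haplotype diversity, shrinkage-corrected pollinator
    mobility proportions), AICc-based single-predictor model comparison
    with Akaike weights and summed factor weights, and a fully seeded
    synthetic landscape and pollination generator so the complete analysis
    runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
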