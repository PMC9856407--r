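Package: mimaspat
Title: Spatial Single-Cell Analysis for Implantable Microdevice Drug-Response Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Downstream spatial single-cell analysis for multiplex
    immunohistochemistry readouts of intratumoral microdose drug delivery
    (microdevice) assays. Provides a synthetic-data generator with planted
    zone-dependent cell composition and marker expression, chromogen image
    quantification (CMYK yellow-channel AEC extraction, watershed nuclear
    segmentation, per-object mean intensities), hierarchical marker-gating
    into standard cell types, drug-source-relative zonal stratification with
    paired enrichment tests against matched control regions, and
    distance-threshold hotspot cluster detection with treatment-specificity
    scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
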