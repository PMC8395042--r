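Package: coastCarbon
Title: Coastal Blue Carbon Accounting from Land-Cover Transitions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for accounting coastal blue carbon storage from
    multi-date categorical land-use/land-cover rasters. Computes
    land-cover transition matrices with transfer-in/out marginals,
    pool-based carbon storage and period sequestration, Fisher-Jenks
    natural-breaks carbon-level maps, per-pixel natural-human
    driving-process chains with their four-way categorization, and a
    z-score-normalized, hierarchically clustered process-by-year carbon
    matrix. Includes a seeded synthetic generator of coastal
    accretion-succession-reclamation dynamics and an end-to-end
    pipeline with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), pheatmap, optparse, withr, knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'lulc-io.R'
    'synthetic-coast.R'
    'transitions.R'
    'carbon-accounting.R'
    'driving-processes.R'
    'process-clustering.R'
    'pipeline.R'
    'coastCarbon-package.R'
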