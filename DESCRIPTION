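Package: spatfcox
Title: Spatial Summary Functions as Functional Covariates in Additive Cox Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for relating the spatial architecture of cells in multiplex
    tissue images to subject-level survival. Computes distance-indexed summary
    functions of marked point patterns (Ripley's K, pair correlation, mark
    connection function, cross-type Moran's I profiles), assembles them into
    per-subject functional covariates, and fits an additive functional Cox
    model in which the log hazard contains an integrated smooth surface of
    distance and curve value, represented by penalized tensor-product cubic
    regression splines with Laplace approximate marginal likelihood smoothing
    selection. Includes a functional-principal-component based survival
    simulation engine for assessing predictive performance of scalar-only,
    functional-only, and combined models, plus seed-deterministic generators
    of two-type planar point patterns and end-to-end synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    yaml
Config/testthat/edition: 3
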