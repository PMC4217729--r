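Package: esrdmap
Title: Small-Area Disease Mapping of End-Stage Renal Disease Incidence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for small-area ecological analysis of end-stage renal
    disease (ESRD) incidence: stratified incidence standardization with
    exact Poisson intervals for standardized incidence ratios, Townsend
    deprivation scoring with quintile covariates, and a from-scratch
    Metropolis-within-Gibbs implementation of the Besag-York-Mollie
    hierarchical model (unstructured heterogeneity plus an intrinsic
    conditional autoregressive spatial effect) with area-level covariates.
    Includes a synthetic registry generator with known ground truth for
    parameter-recovery and calibration studies, and an end-to-end
    pipeline with deterministic manifests and GeoJSON export.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
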