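Package: greengov
Title: Green-Space Governance Analytics: Coverage, Health Effects, Policy
    Strength and Accessibility Equity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline linking urban green-space coverage to
    population health and policy. Computes NDVI, green coverage and patch
    fragmentation from paired reflectance rasters; builds spatial weights and
    tests spatial autocorrelation with permutation-based Moran's I; estimates
    fixed-effects, single-threshold (grid search with residual bootstrap) and
    exact linear-programming quantile panel regressions; fits the spatial
    Durbin model by concentrated maximum likelihood with direct, indirect and
    total effect decomposition; scores coded legal texts into a Policy
    Strength Index and keyword co-occurrence networks into a Policy Coherence
    Index; and measures accessibility equity with population-weighted Lorenz
    curves, Gini coefficients and group gaps. A synthetic-data module
    generates every input with known planted parameters so all estimators are
    testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr,
    igraph
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
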