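Package: nichegrad
Title: Ecological Niche Comparison Along a Crop Domestication Gradient
Version: 0.1.0
Authors@R: person("nichegrad", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing ecological niches of crop domestication
    classes (wild, semiwild, landrace, commercial) in their center of origin.
    Provides a light-weight raster data model (ESRI ASCII grid and single-band
    GeoTIFF), seeded synthetic bioclim-like landscape and occurrence
    generators with known ground-truth niches, spatial thinning and
    environmental extraction for occurrence records, PCA environmental
    envelopes with minimum-convex-hull overlap and bootstrap comparisons, a
    from-scratch presence-background maximum-entropy suitability model with
    L1 regularization (linear, quadratic, hinge and product features, clamped
    logistic output), niche-overlap statistics (Schoener's D, Warren's I,
    Spearman rank correlation) with equivalency and background randomization
    tests, and future-scenario projection bookkeeping: percentile thresholds,
    loss/gain/shift pixel accounting, multi-GCM intersections and
    multivariate environmental similarity surfaces (MESS).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
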