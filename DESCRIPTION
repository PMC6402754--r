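Package: specyield
Title: Hyperspectral Indices, Water Budget and Multivariate Calibration
    for Deficit-Irrigated Wheat
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for estimating spring-wheat biophysical parameters
    (green leaf area, aboveground dry weight, grain yield, water use
    efficiency) from canopy hyperspectral reflectance measured under
    crossed irrigation-rate by plant-density treatments. Implements
    spectral reflectance index computation (twelve two-band normalized
    difference indices plus eight published indices), exhaustive
    dual-wavelength normalized-difference band search with R2 contour
    maps and hotspot extraction, treatment-subset simple regression
    suites, FAO-56 Penman-Monteith reference evapotranspiration with a
    water-balance accounting of seasonal crop evapotranspiration, water
    use efficiency and yield response factor (ky) analysis, and PLSR/SVR
    full-spectrum calibration with leave-one-out cross-validated model
    selection and subset validation. A synthetic-experiment generator
    reproduces the statistical structure of the field design so the
    whole chain is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    igraph,
    jsonlite,
    yaml,
    readxl
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'band-search.R'
    'indices.R'
    'multivariate.R'
    'pipeline.R'
    'regression.R'
    'spectra-io.R'
    'synthetic.R'
    'water-budget.R'
    'yaml-io.R'
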