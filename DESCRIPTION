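Package: carbattrib
Title: Process Attribution of Land Carbon Stock Changes in Model Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for decomposing simulated changes in vegetation and soil
    carbon stocks into input-driven, turnover-driven and interaction
    components, attributing those changes to atmospheric CO2, climate and
    land-use drivers through a four-member factorial scenario design, and
    decomposing multi-model ensemble spread into four process factors
    (baseline input, change in input, baseline turnover, change in
    turnover). Includes a minimal multi-pool land carbon model that
    generates TRENDY-structured synthetic ensembles with known ground
    truth, area-weighted regional aggregation of gridded annual fields,
    soil-system pool aggregation under per-model availability rules, and
    the presentation statistics (spline smoothing, local regression,
    period trends, driver-dominance composites) used to summarise results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mgcv,
    jsonlite
Config/testthat/edition: 3
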