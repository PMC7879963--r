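Package: prevsim
Title: Stock-Flow Simulation and Validation Harness for Chronic Disease
    Prevention Policy Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A population system-dynamics toolkit for cardiovascular and
    related chronic-disease policy analysis. Provides an annual-step
    stock-flow simulation engine driven by declarative YAML model
    specifications, a transparent epidemiological model of non-CVD and
    post-CVD subpopulations with risk-factor relative risks and
    population-attributable-fraction outcome attribution, intervention
    levers with base-versus-scenario differencing, health-economic
    discounting and net-cost arithmetic, a one-way parameter sensitivity
    harness with tornado ordering, and external validation against
    surveillance series with per-measure multiplier recalibration guarded
    against over-calibration. Ships a deterministic desk-scale "toy nation"
    fixture generator and synthetic surveillance panels so the full
    validation cycle runs with no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
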