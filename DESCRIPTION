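Package: oxyaccess
Title: Weekly Supply-Chain Simulation of Patient Access to Therapeutic
    Oxytocin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic weekly simulator of patient access to therapeutic
    oxytocin in a low-income island health system (Zanzibar as the reference
    setting). Combines Arrhenius first-order degradation kinetics of oxytocin
    at pH 4.5 with an odds-ratio-weighted facility-delivery access model,
    postpartum-hemorrhage driven demand, and a FIFO shipment/inventory engine
    to compute the weekly access ratio (effective doses in stock divided by
    the demand they must cover until the next shipment). Provides bisection
    search for the minimal annual supply achieving a target average access
    ratio, multi-year projections under population growth and
    literacy/family-planning interventions, temperature sweeps, a YAML run
    configuration, CSV input/output, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
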