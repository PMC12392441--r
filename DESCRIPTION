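Package: scission
Title: Stochastic Modeling of Hydroxyl-Radical-Induced Polymer Chain Scission
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the progressive scission of water-soluble polymer chains
    (polyethylene glycol) by hydroxyl radicals. Provides closed-form
    pseudo-first-order kinetics for the average number of scissions per chain
    and the number-average molecular weight over time, a stochastic Monte
    Carlo ensemble simulator with chain-length-dependent selection
    probabilities and genealogy tracking, molecular-weight distribution
    summaries (number- and weight-percent histograms, cumulative curves with
    censored end lumps), ingestion of chromatographic oligomer peak tables,
    and grid-search estimation of the scission extent of an experimental
    sample by least-squares fitting of simulated to measured cumulative
    molecular-weight distributions.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
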