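Package: aidscreen
Title: Fitness, Degradation and Chemical-Genetic Interaction Analysis for
    Auxin-Inducible Degron Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse genome-wide auxin-inducible degron (AID)
    libraries in budding yeast: estimation of relative fitness from
    flow-cytometry competition assays (zero-intercept log-ratio slope),
    normalization and four-way degradation classification of dual-gain
    colony-fluorescence arrays, colony-size chemical-genetic interaction
    (CGI) scoring under the multiplicative fitness model with FDR-controlled
    hit calling, and synthetic-data generators that emulate the
    flow-cytometry and 1536-colony-array measurement designs with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
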