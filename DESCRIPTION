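Package: landsec
Title: Land Ecological Security Evaluation with DPSIR, Improved AHP and
    Entropy Weights
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Composite-index assessment of land ecological security from a
    panel of DPSIR (driving force-pressure-state-impact-response) indicators
    observed over a series of years. Implements polarity-aware min-max
    normalization, subjective weighting by a three-scale (0/1/2) improved
    analytic hierarchy process with an optimal transfer matrix, objective
    weighting by information entropy, arithmetic combination of the two
    weight sets, a graded composite security index, and obstacle-degree
    diagnosis of the factors limiting security in each year. Ships the
    Xingtai city (2006-2017) case-study tables as plain-text fixtures and a
    seeded synthetic-panel generator for testing the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
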