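Package: rsbr
Title: Handprint-Footprint Single Scores and the Relative Sustainability
    Benefit Rate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Combines a quantified Human Health handprint (patient DALY
    burden) with an environmental footprint on the three endpoint Areas of
    Protection (Human Health, Ecosystems, Resources) into a dimensionless
    single score via external normalization and panel weighting, and
    compares two scenarios through the Relative Sustainability Benefit
    Rate (RSBR).  Includes hierarchical Monte Carlo sampling over pools of
    normalization and weighting sets, exhaustive enumeration of value-choice
    combinations, one-way sensitivity analysis, a cohort state-transition
    (Markov) engine for generating DALY handprints, built-in pharmaceutical
    case studies with derived reference factors, and CSV/JSON interchange
    formats with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
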