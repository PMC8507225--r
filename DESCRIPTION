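Package: asthmaCE
Title: Markov Cohort Cost-Utility Model for Mild Asthma Reliever Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A weekly-cycle Markov cohort model comparing as-needed
    budesonide-formoterol against low-dose maintenance inhaled corticosteroid
    plus as-needed short-acting beta2-agonist in mild asthma, from a Canadian
    public-payer perspective (2019 CAD). Implements the deterministic base
    case with per-category discounted cost and QALY accrual, probabilistic
    sensitivity analysis with cost-effectiveness acceptability curves, one-way
    deterministic (tornado) sensitivity analysis, eight scenario analyses, and
    structural variants (treatment withdrawal, moderate exacerbations).
    Includes a calibrated Gompertz-Makeham synthetic life-table generator so
    the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
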