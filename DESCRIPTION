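Package: gemfac
Title: Constraint-Based Design of Probiotic Peptide Cell Factories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico pipeline for designing probiotic peptide factories
    with genome-scale metabolic models: a compartmentalized stoichiometric
    model container with SBML (Level 3 + fbc) and TSV input/output, a flux
    balance analysis engine built on a bounded-variable simplex solver,
    single-knockout essentiality screening, minimal-set gap-filling against a
    universal reaction database, sequence-driven construction of heterologous
    peptide biosynthesis pathways (synthesis, secretion and exchange
    reactions), carbon-source growth and production scans with biomass and
    product yield calculations, flux-to-concentration validation arithmetic,
    and four-parameter-logistic IC50 fitting for cytotoxicity dose-response
    data. A synthetic toy-model generator with hand-derived optima makes every
    stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
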