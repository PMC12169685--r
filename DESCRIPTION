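Package: crgreact
Title: Thiol Reactivity Analysis for Covalent Reactive Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for glutathione (GSH) reactivity of covalent
    reactive groups (CRGs) such as alpha-methylene-gamma-lactams and
    acrylamides. Fits pseudo-first-order rate constants to NMR
    reaction-monitoring time series, converts them to half-lives and Eyring
    activation free energies, screens electronic and steric descriptors for
    linear free-energy relationships, trains and validates a single-parameter
    electron-affinity model of thiol reactivity with protonation-state-weighted
    predictions, computes Hammett-type heteroaryl substituent constants from
    carboxylic-acid pKa differences, and analyses papain inactivation assays
    (initial rates, residual activity, reactivity correlations). Includes
    seeded synthetic-data generators emulating each experimental design so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
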