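Package: AbViscosity
Title: Sequence-Based Viscosity Scoring and Charge-Patch Mutation Design
    for Therapeutic Antibodies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for engineering low-viscosity therapeutic antibodies.
    Implements Henderson-Hasselbalch side-chain charge models over
    Kabat-numbered variable domains (Fv net charge, charge asymmetry,
    Eisenberg hydrophobicity index and the derived sequence-based viscosity
    score), Ross-Minton concentration-viscosity curve fitting with exact
    inversion and delta-method confidence intervals for the concentration at
    a viscosity threshold, a two-round in-silico mutation triage pipeline
    (stability/affinity tolerance, CDR substitution rules, germline-frequency
    framework filtering, score-reduction and charge-patch prioritisation
    with heavy/light chain combination), and correlation analysis of
    predictor panels against measured viscosity endpoints.  Ships a fully
    validated 38-variant anti-PDGF-BB design panel with parental VH/VL
    sequences and Kabat numbering fixtures, plus seeded synthetic-data
    generators for viscosity curves and candidate-mutation tables.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
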