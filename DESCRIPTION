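Package: gmcskit
Title: Genetic Minimal Cut Set Enumeration for Constraint-Based Metabolic Models
Version: 0.1.0
Authors@R:
    person("gmcskit", "developers", email = "gmcskit@example.org", role = c("aut", "cre"))
Description: Enumerates genetic minimal cut sets (gMCSs) -- essential genes,
    synthetic-lethal gene sets, and growth-coupling gene interventions -- in
    constraint-based metabolic models. Gene-protein-reaction rules are parsed
    and converted between disjunctive and conjunctive normal forms to obtain
    per-reaction gene cut sets; gMCSs of a target flux region are then found
    by incrementally building a k-representative subset of the region,
    combining a cardinality-capped Berge minimal-hitting-set algorithm with
    linear-programming feasibility checks of candidate knockouts. Readers for
    SBML (fbc) and COBRA JSON models, target-region builders for lethality and
    growth-coupling studies, and a command-line driver are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    Matrix,
    methods,
    stats,
    utils,
    tools,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
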