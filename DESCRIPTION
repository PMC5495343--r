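Package: zsynkin
Title: Zsyntax Pathway Deduction and Mass-Action Reaction Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Executable toolkit for formal reasoning about molecular pathways
    and reaction kinetics. Implements the Zsyntax deduction calculus (recursive
    matching of empirically valid formulae over aggregates of molecular
    interactions, with a brute-force fixpoint oracle for property testing) and
    a mass-action kinetics engine (flux vectors, stoichiometric matrices,
    assembly of reaction rate equations d[X]/dt = N v, numerical simulation,
    and residual verification of closed-form solutions). Ships a catalog of
    worked models: four generic consecutive-reaction schemes with their
    analytic solutions, the TP53 phosphorylation and cancer-stem-cell death
    pathways, and two cancer-stem-cell tumor growth compartment models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
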