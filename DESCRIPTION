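Package: idream
Title: Integrating Inferred Transcription-Factor Influence Networks with
    Constraint-Based Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds integrated regulatory-metabolic models that predict the
    growth phenotypes of transcription-factor knockouts. A transcription-factor
    influence network is inferred from expression compendia by bootstrap sparse
    regression with a per-edge false discovery rate, and converted into
    probabilistic flux-retention constraints on a stoichiometric metabolic
    model (the IDREAM scheme, with the PROM conditional-probability scheme and
    an IDREAM/PROM hybrid as alternatives). Includes flux balance analysis and
    flux variability analysis via an internal simplex solver, gene-protein-
    reaction rule evaluation and gene deletion, double-perturbation scanning
    for synthetic genetic interactions, evaluation statistics (Matthews
    correlation, ROC/AUC, Fisher-Z correlation comparison, permutation nulls),
    and seeded generators for synthetic regulatory-metabolic benchmark systems.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    glmnet,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
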