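Package: phbrsel
Title: MHC Presentation Scores and Immunogenic Selection Analysis for
    Cancer Hot Spot Mutations
Version: 0.1.0
Authors@R:
    person("Maarten", "Roels", email = "maarten.roels@example.org",
           role = c("aut", "cre"))
Description: Tools to test whether apparent immunogenic selection against
    cancer driver mutations is explained by MHC genotype variation or by
    intrinsic properties of a handful of common hot spot mutations.
    Implements Patient Harmonic Best Rank (PHBR) scoring of missense
    mutations from peptide-window rank tables, isogenotypic virtual-patient
    cohort simulation, paired random-intercept logistic regression models
    with matrix randomization controls, a leave-one-out odds-ratio
    attribution scan, and a substitution/amino-acid-context atlas built
    from the single-nucleotide-reachable missense substitution space.
    Synthetic rank predictors and scenario generators make the whole
    pipeline testable without external affinity-prediction software.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    lme4,
    stats,
    utils
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
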