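Package: immunoprey
Title: Predator-Prey Simulation of Tumor Immunopeptidome and CTL Clonal Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hybrid deterministic-stochastic simulator of coupled tumor and
    adaptive immune dynamics. Tumor cell lineages grow logistically with
    lineage-specific, saturable CTL-mediated killing; antigen-specific CTL
    clones expand on immunogenicity-weighted antigen stimulus while competing
    with a pooled tumor-ignorant population for a shared nonspecific stimulus.
    Neoantigen feature vectors (MHC binding affinity, binding stability,
    agretopicity, transcript abundance, foreignness) are sampled from a
    Gaussian copula with zero- and one-inflated beta foreignness, filtered by
    TESLA-style immunogenicity criteria, and assigned truncated-exponential
    immunogenicity scores. Immunopeptidomes evolve through stochastic
    neoantigen gain, neoantigen loss, and MHC allele loss events with lineage
    branching. Includes mouse and human presets, immune checkpoint blockade
    treatment, virtual-cohort trials with RECIST-style response
    classification, biomarker analyses, and a local sensitivity analysis
    harness.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    jsonlite,
    yaml,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
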