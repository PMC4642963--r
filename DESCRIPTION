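Package: enhancerun
Title: Enhancer Runaway: Theory and Simulation of Cis-Regulatory Strength
    Escalation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Population-genetics toolkit for the enhancer-runaway process in
    diploids, in which homologous cis-regulatory alleles compete for
    expression of the gene they control.  Provides the closed-form fitness and
    effective-dominance calculus for allele-specific expression, exact and
    linearized deterministic two-locus dynamics with the masking/purging
    decomposition of selection on an enhancer, diffusion-approximation
    fixation probabilities for enhancer-strength mutants, and fast
    individual-based Wright-Fisher simulators (constant total expression,
    gene-dosage stabilizing selection, enhancer/transcription-factor
    coevolution, and partial selfing), together with escalation-rate
    (doubling-time) analytics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
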