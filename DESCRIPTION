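Package: domrev
Title: Dominance Reversals at Antagonistic Polymorphisms: Models, Simulation
    and Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying beneficial reversals of dominance at
    antagonistic polymorphisms. Implements a biophysically explicit
    cis-regulatory dominance-modifier model (thermodynamic transcription-factor
    occupancy with mismatch-dependent binding) evolved under sexually
    antagonistic selection in forward-time individual-based Wright-Fisher
    simulations; a deterministic two-sex single-locus viability model with
    invasion analysis and protected-polymorphism classification; composition of
    genotype-phenotype and phenotype-fitness maps to classify effective
    dominance (including marginal overdominance and net underdominance); and
    two detection methods: dominance ordination of inbred strain panels via
    diallel array covariances with a cross-context permutation test, and an
    allele-specific-expression reversal caller based on per-context exact
    binomial tests. Synthetic-data generators with ground-truth labels make
    every method testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
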