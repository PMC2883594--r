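Package: cisevolve
Title: In Silico Evolutionary Design of Auto-Regulatory Cis-Regulatory Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-level thermodynamic modelling and in silico evolution of
    bacterial cis-regulatory regions that may regulate their own transcription.
    Binding free energies of transcription factors and RNA polymerase are
    computed from nucleotide and amino-acid sequences, equilibrium promoter
    occupancy is obtained from a Shea-Ackers style partition function evaluated
    by dynamic programming over all non-overlapping binding configurations
    (with cooperativity and regulated recruitment), and the steady-state output
    of the regulated gene follows from a one-dimensional production-degradation
    differential equation. On top of this engine the package provides
    transcriptional logic-gate goal functions, multi-objective fitness scores
    (response shape, response time, intrinsic noise), a mutation-selection
    evolutionary algorithm, closed-form minimal models with sensitivity
    analysis, and post-hoc promoter analyses: computational DNA footprints,
    binding-site calling, model simplification and a feedback measure
    quantifying the degree of auto-regulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse,
    Biostrings
Config/testthat/edition: 3
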