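Package: siglogic
Title: Boolean Logic Models of Signaling from Perturbation Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains genotype-specific Boolean logic models of intracellular
    signaling from cue-sentinel-response perturbation datasets. Provides
    readers for signed causal interaction networks (SIF and SIGNOR-style
    tables), normalization of bead-array median fluorescence intensities to
    the unit interval with per-analyte Hill functions, prior-knowledge
    network compression and AND/OR hypergraph expansion, data-driven edge
    imputation, a synchronous Boolean simulator with steady-state and cycle
    detection, genetic-algorithm model-family optimization with edge
    confidence, in silico single and combinatorial knockout screens with
    phenotype (apoptosis/proliferation) scoring and rescue calling, and
    patient-specific simulations from binarized mutational profiles,
    including FLT3 internal-tandem-duplication domain classification. A
    synthetic ground-truth generator emulates the multiparametric
    experimental design so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
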