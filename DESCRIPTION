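Package: polkin
Title: Kinetic Modeling of RNA Polymerase II Initiation, Elongation,
    Processivity and Termination from Nascent-Transcription Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies RNA polymerase II transcription kinetics from
    windowed nascent-transcription data. Provides a deterministic ODE
    simulator of polymerase occupancy along a discretized gene (occupancy,
    4sU-seq and DRB-4sU-seq readouts), strand-aware genomic window counting
    with spike-in normalization, a local fold-change likelihood regression
    for gene-body processivity defects, negative-binomial regressions for
    post-polyadenylation-site termination rates and for DRB-4sU-seq
    wavefront (elongation rate) estimation with an expression-dependent
    background prior, closed-form kinetic fits of SLAM-seq new/old RNA
    levels (synthesis and degradation rates), transcription completion and
    readthrough scores with a moderated differential test, data-driven
    transcription-unit annotation, a synthetic-data generator with known
    ground truth, and an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    minpack.lm,
    rtracklayer,
    stats,
    utils
Suggests:
    DESeq2,
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
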