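Package: olivoseq
Title: Multimodal Patch-Seq Analysis of Auditory Brainstem Neurons
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
        role = c("aut", "cre"))
Description: Tools for multimodal patch-seq studies of the lateral superior
    olive (LSO), where whole-cell electrophysiology and single-cell RNA-seq
    are obtained from the same neurons. The package extracts intrinsic and
    synaptic electrophysiological features (input resistance, membrane time
    constant, rheobase, firing pattern, voltage sag, spontaneous PSC
    kinetics) from stimulus-tagged traces, performs single-cell count
    preprocessing (MAD-based cell QC, gene filtering, deconvolution size
    factors, TPM), consensus clustering with silhouette-based model
    selection, differential expression with AUROC ranking and
    fold-change/TPM gating (DEGs, Super DEGs, Cluster similarity with a
    kernel-density overlapping index), gene-panel and neurotransmitter
    combination summaries, and transcriptomic-electrophysiological
    congruence analysis. A negative-binomial count and parametric trace
    simulator with full ground truth makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    scran,
    cluster,
    igraph,
    mclust,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: SingleCell, RNASeq, Clustering, DifferentialExpression,
    Normalization
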