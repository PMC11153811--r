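#' Run the full multimodal analysis pipeline on a simulated study
#'
#' End-to-end orchestration mirroring the patch-seq workflow: simulate
#' counts and per-cell traces, extract electrophysiological features, run
#' cell QC and gene filtering, compute deconvolution size factors,
#' normalized log2 counts and TPM, select highly variable genes, perform
#' consensus clustering with silhouette-based selection of k (checked
#' against graph-based clustering), call DEGs / Super DEGs / Cluster
#' similarity with the overlapping index, summarize the neurotransmitter
#' panel, and measure transcriptomic-electrophysiological congruence.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param seed integer master seed (default \code{config@seed}).
#' @param nHVG highly variable genes used for clustering.
#' @param kRange candidate cluster counts.
#' @param protocols trace protocols to simulate for feature extraction;
#'   drop \code{"psc"} for a faster run without synaptic features.
#' @param outDir optional directory; when given, the counts, feature,
#'   label, silhouette, DE and similarity tables are written as
#'   CSV/MTX/JSON together with a manifest of parameters, seeds and file
#'   hashes.
#' @param verbose print one status line per stage.
#' @return list with \code{sce} (QC'd, normalized, TPM), \code{truth},
#'   \code{features}, \code{qc}, \code{hvgs}, \code{clustering}
#'   (\linkS4class{ConsensusResult}), \code{graphLabels}, \code{agreement},
#'   \code{de}, \code{similarity}, \code{panel}, \code{combos},
#'   \code{congruence} and \code{summary} (cluster sizes, k table, DEG /
#'   Super DEG / similar counts, congruent fraction).
#' @export
runPipeline <- function(config = simConfig(), seed = config@seed,
                        nHVG = 1000, kRange = 2:10,
                        protocols = c("rest", "step", "vc_step", "psc"),
                        outDir = NULL, verbose = TRUE) {
    say <- function(...) if (verbose) message(sprintf(...))
    t0 <- proc.time()[["elapsed"]]
    stage <- function(nm, expr) {
        res <- tryCatch(expr, error = function(e)
            stop("pipeline stage '", nm, "' failed: ",
                 conditionMessage(e), call. = FALSE))
        say("[%s] done (%.1f s)", nm, proc.time()[["elapsed"]] - t0)
        res
    }

    sim <- stage("simulate", simulateCounts(config, seed = seed))
    truth <- sim$truth

    features <- stage("ephys-features",
        simulateFeatures(config, truth, protocols = protocols,
                         seed = seed + 1000L))

    qc <- stage("cell-qc", cellQCFilter(sim$sce))
    sce <- stage("gene-filter", geneFilter(qc$sce))
    sf <- stage("size-factors", computeSizeFactors(sce))
    sce <- stage("normalize", normalizeCounts(sce, sf))
    sce <- stage("tpm", computeTPM(sce))
    hvgs <- stage("hvg", selectHVGs(sce, n = nHVG))

    lm <- as.matrix(SingleCellExperiment::logcounts(sce))[hvgs, ,
                                                          drop = FALSE]
    clus <- stage("consensus-cluster",
                  consensusCluster(lm, kRange = kRange, seed = seed))
    gl <- stage("graph-cluster", graphCluster(lm, seed = seed))
    agree <- clusterAgreement(clusterLabels(clus), gl)

    tpm <- as.matrix(SummarizedExperiment::assay(sce, "tpm"))
    # downstream contrasts are defined between the two principal clusters;
    # if the silhouette selected another k, use the two-cluster cut
    labels <- if (clus@kSelected == 2L) clusterLabels(clus) else {
        warning("silhouette selected k = ", clus@kSelected,
                "; using the 2-cluster consensus cut for DE/congruence")
        consensusLabelsAt(clus, 2L)
    }
    norm <- as.matrix(SingleCellExperiment::logcounts(sce))
    de <- stage("differential-expression",
                differentialExpression(norm, tpm, labels))
    sim2 <- rankSimilarity(de, tpm, labels)

    classes <- cellClass(truth)[match(colnames(sce),
                                      trueEphys(truth)$cell)]
    cohorts <- makeCohorts(classes, labels)
    panel <- stage("panels",
                   panelSummary(tpm, cohorts, loadPanel("nt7")))
    combos <- transmitterCombinations(tpm, labels, classes = classes)

    fcls <- features$firing_class[match(colnames(sce), features$cell)]
    cong <- stage("congruence", congruence(labels, fcls))

    summary <- list(
        n_cells = ncol(sce), n_genes = nrow(sce),
        cells_removed = sum(qc$report$removed),
        k_selected = clus@kSelected,
        silhouette_by_k = silhouetteByK(clus),
        cluster_sizes = as.integer(table(labels)),
        n_deg = sum(de$is_deg), n_super_deg = sum(de$is_super_deg),
        n_similar = sum(de$is_cluster_similar),
        method_agreement = agree$ari,
        congruent_fraction = cong$fraction)

    out <- list(sce = sce, truth = truth, features = features, qc = qc,
                hvgs = hvgs, clustering = clus, graphLabels = gl,
                agreement = agree, de = de, similarity = sim2,
                panel = panel, combos = combos, congruence = cong,
                summary = summary)

    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        writeCountsDir(sce, file.path(outDir, "counts"))
        writeFeatures(features, file.path(outDir, "features.csv"))
        write.csv(data.frame(cell = colnames(sce), cluster = labels,
                             firing_class = fcls),
                  file.path(outDir, "labels.csv"), row.names = FALSE)
        write.csv(data.frame(k = names(silhouetteByK(clus)),
                             avg_silhouette = silhouetteByK(clus)),
                  file.path(outDir, "silhouette.csv"), row.names = FALSE)
        write.csv(.fmtNum(de), file.path(outDir, "de.csv"),
                  row.names = FALSE)
        write.csv(.fmtNum(sim2), file.path(outDir, "similarity.csv"),
                  row.names = FALSE)
        jsonlite::write_json(qc$report,
                             file.path(outDir, "qc_report.json"),
                             dataframe = "rows", auto_unbox = TRUE)
        params <- list(nOnset = config@nOnset,
                       nSustained = config@nSustained,
                       nDelayed = config@nDelayed, nGenes = config@nGenes,
                       nHVG = nHVG, kRange = range(kRange))
        jsonlite::write_json(.runManifest(outDir, seed, params),
                             file.path(outDir, "manifest.json"),
                             auto_unbox = TRUE)
    }
    out
}

# fixed 6-significant-digit formatting for deterministic CSV output
.fmtNum <- function(df) {
    for (j in seq_along(df))
        if (is.numeric(df[[j]])) df[[j]] <- signif(df[[j]], 6)
    df
}
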