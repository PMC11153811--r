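#' @importFrom utils read.delim write.csv read.csv
NULL

#' List the built-in gene panels
#'
#' Panels ship as editable TSV resources (gene symbol + optional protein
#' name) covering the channel and receptor families commonly profiled in
#' auditory brainstem neurons: voltage-gated K (alpha and regulatory), Na,
#' Ca, TRP and HCN channels, ligand-gated receptors, GPCRs, and the 7-gene
#' neurotransmitter panel (vGLUT2, GlyT2, GAD65, DDC, ChAT, CGRP,
#' urocortin).
#'
#' @return character vector of panel names.
#' @export
listPanels <- function() {
    files <- dir(system.file("extdata", "panels", package = "olivoseq"),
                 pattern = "\\.tsv$")
    sub("\\.tsv$", "", files)
}

#' Load a built-in gene panel
#'
#' @param name panel name (see \code{\link{listPanels}}), or a path to a
#'   user TSV with a \code{gene} column.
#' @return character vector of gene symbols (unique, input order).
#' @examples
#' loadPanel("nt7")
#' @export
loadPanel <- function(name) {
    path <- if (file.exists(name)) name else
        system.file("extdata", "panels", paste0(name, ".tsv"),
                    package = "olivoseq")
    if (!nzchar(path) || !file.exists(path))
        stop("unknown panel: ", name)
    tab <- read.delim(path, stringsAsFactors = FALSE)
    if (!"gene" %in% names(tab)) stop("panel TSV needs a 'gene' column")
    unique(tab$gene)
}

#' Build the standard analysis cohorts
#'
#' The five reporting cohorts: the three firing classes, transcriptomic
#' cluster 1 (Onset + Sustained) and all neurons; cluster 2 is included for
#' completeness.
#'
#' @param classes per-cell firing-class labels.
#' @param clusters per-cell cluster labels (1/2), same order.
#' @return named list of logical index vectors.
#' @export
makeCohorts <- function(classes, clusters) {
    if (length(classes) != length(clusters))
        stop("classes and clusters must align")
    list(Onset = classes == "Onset",
         Sustained = classes == "Sustained",
         Delayed = classes == "Delayed",
         Cluster1 = clusters == 1,
         Cluster2 = clusters == 2,
         All = rep(TRUE, length(classes)))
}

.panelRows <- function(tpm, panel) {
    present <- intersect(panel, rownames(tpm))
    missing <- setdiff(panel, rownames(tpm))
    if (length(missing))
        message("panel genes absent from the matrix: ",
                paste(missing, collapse = ", "))
    list(present = present, missing = missing)
}

#' Per-cohort panel expression summary
#'
#' For every panel gene and cohort: mean TPM and the percentage of cells
#' expressing the gene at each threshold (default thresholds 1 and
#' 10 TPM).  Genes missing from the matrix are reported via a message, not
#' silently dropped.
#'
#' @param tpm genes x cells TPM matrix.
#' @param cohorts named list of logical / integer cell indices (see
#'   \code{\link{makeCohorts}}).
#' @param panel character vector of gene ids.
#' @param thresholds TPM thresholds for "percent expressing".
#' @return tidy data.frame: cohort, gene, mean_tpm, pct_ge<threshold> ...
#' @export
panelSummary <- function(tpm, cohorts, panel, thresholds = c(1, 10)) {
    pr <- .panelRows(tpm, panel)
    rows <- list()
    for (co in names(cohorts)) {
        idx <- cohorts[[co]]
        sub <- tpm[pr$present, idx, drop = FALSE]
        r <- data.frame(cohort = co, gene = pr$present,
                        n_cells = sum(idx),
                        mean_tpm = rowMeans(sub))
        for (th in thresholds)
            r[[sprintf("pct_ge%g", th)]] <- 100 * rowMeans(sub >= th)
        rows[[co]] <- r
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Panel genes expressed per cell
#'
#' Counts, for each cell, how many panel genes are expressed at
#' \code{threshold} TPM or more, and summarizes per cohort (mean, range,
#' frequency histogram).  Both the panel size and the number of panel genes
#' expressed anywhere in the sample are reported as denominators.
#'
#' @inheritParams panelSummary
#' @param threshold TPM expression threshold (default 1).
#' @return list with \code{perCell} (named counts), \code{summary}
#'   (cohort, mean, min, max), \code{histogram} (cohort x count table),
#'   \code{panelSize} and \code{expressedInSample}.
#' @export
genesPerCell <- function(tpm, cohorts, panel, threshold = 1) {
    pr <- .panelRows(tpm, panel)
    sub <- tpm[pr$present, , drop = FALSE]
    cnt <- colSums(sub >= threshold)
    summ <- do.call(rbind, lapply(names(cohorts), function(co) {
        x <- cnt[cohorts[[co]]]
        data.frame(cohort = co, mean = mean(x), min = min(x),
                   max = max(x))
    }))
    hist <- table(
        cohort = rep(names(cohorts),
                     times = vapply(cohorts, sum, numeric(1))),
        n_genes = unlist(lapply(cohorts, function(i) cnt[i])))
    list(perCell = cnt, summary = summ, histogram = hist,
         panelSize = length(panel),
         expressedInSample = sum(rowSums(sub >= threshold) > 0))
}

#' Neurotransmitter gene combinations per cell
#'
#' Each cell's expressed subset of the panel (TPM >= \code{threshold})
#' defines its combination; combinations are enumerated with per-cluster
#' counts and percentages (cells expressing nothing count as the empty
#' combination, so percentages sum to 100 within each cluster).  Set sizes
#' (percent of cells expressing each gene) and per-cohort mean combination
#' sizes are included -- the UpSet-plot data.
#'
#' @param tpm genes x cells TPM matrix.
#' @param clusters per-cell cluster labels (1/2).
#' @param panel gene ids (default the 7 neurotransmitter genes).
#' @param threshold TPM threshold (default 1).
#' @param classes optional per-cell firing classes for per-class mean
#'   combination sizes.
#' @return list with \code{combinations} (combination, per-cluster count
#'   and percent), \code{membership} (cells x genes logical matrix),
#'   \code{setSizes}, \code{meanComboSize} per cluster (and per class when
#'   \code{classes} given), and \code{maxComboSize} per cluster.
#' @export
transmitterCombinations <- function(tpm, clusters, panel = loadPanel("nt7"),
                                    threshold = 1, classes = NULL) {
    pr <- .panelRows(tpm, panel)
    memb <- t(tpm[pr$present, , drop = FALSE] >= threshold)
    combo <- apply(memb, 1, function(r)
        if (!any(r)) "(none)" else
            paste(pr$present[r], collapse = "+"))
    sizes <- rowSums(memb)
    lev <- sort(unique(clusters))
    tab <- table(combo, factor(clusters, levels = lev))
    comb <- data.frame(combination = rownames(tab))
    for (cl in lev) {
        comb[[sprintf("count_c%s", cl)]] <- as.integer(tab[, as.character(cl)])
        comb[[sprintf("pct_c%s", cl)]] <-
            100 * tab[, as.character(cl)] / sum(clusters == cl)
    }
    comb$size <- vapply(strsplit(comb$combination, "+", fixed = TRUE),
                        function(s) if (identical(s, "(none)")) 0L
                                    else length(s), integer(1))
    comb <- comb[order(-rowSums(tab)), ]
    rownames(comb) <- NULL
    meanSize <- vapply(lev, function(cl)
        mean(sizes[clusters == cl]), numeric(1))
    names(meanSize) <- paste0("Cluster", lev)
    if (!is.null(classes)) {
        byClass <- vapply(sort(unique(classes)), function(cc)
            mean(sizes[classes == cc]), numeric(1))
        meanSize <- c(meanSize, byClass)
    }
    maxSize <- vapply(lev, function(cl)
        max(sizes[clusters == cl]), numeric(1))
    names(maxSize) <- paste0("Cluster", lev)
    list(combinations = comb, membership = memb,
         setSizes = 100 * colMeans(memb),
         meanComboSize = meanSize, maxComboSize = maxSize,
         nCombinations = nrow(comb))
}

#' Most highly expressed genes
#'
#' Genes ranked by mean TPM over all retained neurons (ties broken by gene
#' id), with per-cohort means alongside.
#'
#' @param tpm genes x cells TPM matrix.
#' @param n number of genes to return.
#' @param cohorts optional named cohort list for per-cohort means.
#' @return data.frame: rank, gene, mean_tpm and per-cohort means.
#' @export
topExpressed <- function(tpm, n = 50, cohorts = NULL) {
    if (n > nrow(tpm)) stop("n exceeds the gene count")
    mu <- rowMeans(tpm)
    o <- order(-mu, rownames(tpm))[seq_len(n)]
    out <- data.frame(rank = seq_len(n), gene = rownames(tpm)[o],
                      mean_tpm = mu[o])
    if (!is.null(cohorts))
        for (co in names(cohorts))
            out[[paste0("mean_", co)]] <-
                rowMeans(tpm[o, cohorts[[co]], drop = FALSE])
    rownames(out) <- NULL
    out
}
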