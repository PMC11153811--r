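#' @importFrom SummarizedExperiment assay assays assays<- assay<- rowData
#'   colData
#' @importFrom SingleCellExperiment SingleCellExperiment logcounts
#'   logcounts<- sizeFactors sizeFactors<-
NULL

.counts <- function(sce) as.matrix(assay(sce, "counts"))

#' MAD-based cell quality filtering
#'
#' Per-cell total counts and detected-gene counts are log2-transformed; a
#' cell is removed when either metric falls more than \code{nmads} scaled
#' median absolute deviations (consistency constant 1.4826, one pass) below
#' the median.  Low-depth libraries such as negative controls fail this
#' filter.
#'
#' @param sce a \code{SingleCellExperiment} with a \code{"counts"} assay.
#' @param nmads outlier distance in MADs (default 3).
#' @return list with \code{sce} (retained cells) and \code{report}, a
#'   data.frame of per-cell metrics with a \code{removed} flag and the
#'   reason.
#' @export
cellQCFilter <- function(sce, nmads = 3) {
    m <- .counts(sce)
    if (ncol(m) < 4L) stop("cell QC needs at least 4 cells")
    total <- colSums(m)
    detected <- colSums(m >= 1L)
    lt <- log2(total + 1)
    ld <- log2(detected + 1)
    lowT <- lt < median(lt) - nmads * mad(lt)
    lowD <- ld < median(ld) - nmads * mad(ld)
    removed <- lowT | lowD
    report <- data.frame(cell = colnames(m), total = total,
                         detected = detected, log2_total = lt,
                         log2_detected = ld, low_counts = lowT,
                         low_features = lowD, removed = removed,
                         row.names = colnames(m))
    if (all(removed))
        stop("cell QC removed every cell; check the input depth profile")
    list(sce = sce[, !removed], report = report)
}

#' Expression-based gene filtering
#'
#' Keeps genes detected (count >= \code{minCount}) in at least
#' \code{minFraction} of the cells (default: at least one count in at least
#' 5\% of the neurons, the cutoff applied after cell QC).  An alternative
#' reading of the rule -- mean count of at least one across all cells -- is
#' available via \code{rule = "mean"}.
#'
#' @param sce a \code{SingleCellExperiment} (cell-QC'd).
#' @param minFraction fraction of cells for the detection rule.
#' @param minCount detection threshold per cell.
#' @param rule \code{"detected"} (default) or \code{"mean"}.
#' @return the row-subsetted \code{SingleCellExperiment}.
#' @export
geneFilter <- function(sce, minFraction = 0.05, minCount = 1,
                       rule = c("detected", "mean")) {
    rule <- match.arg(rule)
    m <- .counts(sce)
    keep <- if (rule == "detected") {
        rowSums(m >= minCount) >= ceiling(minFraction * ncol(m))
    } else {
        rowMeans(m) >= minCount
    }
    if (!any(keep)) stop("gene filter retained zero genes")
    sce[keep, ]
}

#' Per-cell size factors
#'
#' Deconvolution size factors (cells pooled, pool-level factors against the
#' average pseudo-cell, per-cell factors solved from the pooled system;
#' pool sizes 21/26/31 clipped to the cell count) computed via
#' \code{scran}; with fewer than 20 cells the method falls back to
#' library-size factors with a warning.  Factors are rescaled to geometric
#' mean 1, and any non-positive deconvolution solution falls back to
#' library size for the run with a warning.
#'
#' @param sce a \code{SingleCellExperiment}.
#' @param method \code{"deconvolution"} or \code{"libsize"}.
#' @return numeric vector of positive size factors, geometric mean 1.
#' @export
computeSizeFactors <- function(sce,
                               method = c("deconvolution", "libsize")) {
    method <- match.arg(method)
    m <- .counts(sce)
    n <- ncol(m)
    libf <- colSums(m)
    if (any(libf == 0)) stop("cells with zero total counts present")
    if (method == "deconvolution" && n < 20L) {
        warning("fewer than 20 cells: falling back to library-size factors")
        method <- "libsize"
    }
    sf <- if (method == "deconvolution") {
        sizes <- unique(pmin(c(21L, 26L, 31L), n))
        res <- tryCatch(
            scran::calculateSumFactors(m, sizes = sizes, positive = TRUE,
                                       min.mean = 0.1),
            error = function(e) {
                warning("deconvolution failed (", conditionMessage(e),
                        "); using library-size factors")
                libf
            })
        if (any(res <= 0)) {
            warning("non-positive deconvolution factors; ",
                    "using library-size factors for those cells")
            res[res <= 0] <- libf[res <= 0] / mean(libf)
        }
        res
    } else libf
    sf <- sf / exp(mean(log(sf)))
    names(sf) <- colnames(m)
    sf
}

#' Size-factor normalization on the log2 scale
#'
#' \code{value = log2(count / sizeFactor + 1)}.
#'
#' @param sce a \code{SingleCellExperiment}.
#' @param sizeFactors positive per-cell factors (default: computed by
#'   \code{\link{computeSizeFactors}}).
#' @return the \code{SingleCellExperiment} with a \code{"logcounts"} assay
#'   and the size factors recorded.
#' @export
normalizeCounts <- function(sce, sizeFactors = NULL) {
    if (is.null(sizeFactors)) sizeFactors <- computeSizeFactors(sce)
    if (any(sizeFactors <= 0)) stop("size factors must be positive")
    m <- .counts(sce)
    logcounts(sce) <- log2(sweep(m, 2, sizeFactors, "/") + 1)
    sizeFactors(sce) <- sizeFactors
    sce
}

#' Transcripts per million
#'
#' Counts are divided by gene length in kb, then each cell's length-
#' normalized rates are scaled to sum to one million:
#' \eqn{TPM_{gc} = 10^6 \, r_{gc} / \sum_g r_{gc}} with
#' \eqn{r_{gc} = count_{gc} / length_g[kb]}.  Computed on the post-filter
#' matrix.
#'
#' @param sce a \code{SingleCellExperiment} whose \code{rowData} carries a
#'   \code{length} column in bp.
#' @return the \code{SingleCellExperiment} with a \code{"tpm"} assay.
#' @export
computeTPM <- function(sce) {
    len <- rowData(sce)$length
    if (is.null(len) || any(len <= 0))
        stop("rowData(sce)$length (bp) required for TPM")
    m <- .counts(sce)
    if (any(colSums(m) == 0))
        stop("zero-count cell: TPM undefined")
    rate <- m / (len / 1000)
    tpm <- sweep(rate, 2, colSums(rate), "/") * 1e6
    assays(sce)$tpm <- tpm
    sce
}

#' Select highly variable genes
#'
#' Fits a mean--variance trend to the normalized log2 expression values by a
#' rolling median of the per-gene variance ordered by mean expression, and
#' ranks genes by their variance residual above the trend.
#'
#' @param sce a \code{SingleCellExperiment} with \code{"logcounts"}.
#' @param n number of genes to return (default 1000, capped at the gene
#'   count).
#' @param span rolling window width as a fraction of genes.
#' @return character vector of gene ids, ordered by decreasing residual.
#' @export
selectHVGs <- function(sce, n = 1000, span = 0.1) {
    lm <- as.matrix(logcounts(sce))
    mu <- rowMeans(lm)
    v <- apply(lm, 1, stats::var)
    n <- min(n, nrow(lm))
    o <- order(mu)
    k <- max(5L, round(span * length(mu)))
    if (k %% 2L == 0L) k <- k + 1L
    trend <- numeric(length(mu))
    trend[o] <- stats::runmed(v[o], k, endrule = "median")
    resid <- v - trend
    head(rownames(lm)[order(resid, decreasing = TRUE)], n)
}
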