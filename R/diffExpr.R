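#' @importFrom stats pt p.adjust density bw.nrd0 var
NULL

#' Per-gene Welch t-tests between two clusters
#'
#' Vectorized Welch two-sample t-tests on normalized log2 expression.  The
#' log2 fold change is the difference of cluster means (cluster 1 minus
#' cluster 2).  A variance floor of \code{varFloor} on both groups prevents
#' zero division for constant genes; a gene constant and equal in both
#' groups gets p = 1.
#'
#' @param nm genes x cells normalized log2 matrix.
#' @param labels per-cell cluster labels with exactly two levels; the
#'   smaller level (after sorting) is "cluster 1".
#' @param varFloor variance floor (default 1e-8).
#' @return data.frame with \code{gene}, \code{mean_log_c1},
#'   \code{mean_log_c2}, \code{log2fc}, \code{t_stat}, \code{df},
#'   \code{p_value}.
#' @export
welchTests <- function(nm, labels, varFloor = 1e-8) {
    lev <- sort(unique(labels))
    if (length(lev) != 2L) stop("labels must have exactly two levels")
    g1 <- labels == lev[1]; g2 <- labels == lev[2]
    n1 <- sum(g1); n2 <- sum(g2)
    if (n1 < 3L || n2 < 3L) stop("both clusters need at least 3 cells")
    m1 <- rowMeans(nm[, g1, drop = FALSE])
    m2 <- rowMeans(nm[, g2, drop = FALSE])
    v1 <- pmax(apply(nm[, g1, drop = FALSE], 1, var), varFloor)
    v2 <- pmax(apply(nm[, g2, drop = FALSE], 1, var), varFloor)
    se2 <- v1 / n1 + v2 / n2
    t <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * pt(abs(t), df, lower.tail = FALSE)
    data.frame(gene = rownames(nm), mean_log_c1 = m1, mean_log_c2 = m2,
               log2fc = m1 - m2, t_stat = t, df = df, p_value = p,
               row.names = rownames(nm))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate control.
#'
#' @param p p-values in [0, 1].
#' @return FDR values.
#' @export
bhAdjust <- function(p) p.adjust(p, method = "BH")

#' Per-gene AUROC for cluster-1 membership
#'
#' Rank-based area under the receiver-operating characteristic curve for
#' "expression predicts cluster-1 membership": the Mann-Whitney U statistic
#' divided by \eqn{n_1 n_2}, with ties contributing weight 0.5 through
#' midranks.  1 means perfectly higher in cluster 1, 0 perfectly higher in
#' cluster 2, 0.5 uninformative.
#'
#' @param nm genes x cells matrix.
#' @param labels two-level labels, smaller sorted level = cluster 1.
#' @return numeric AUROC per gene.
#' @export
aurocScores <- function(nm, labels) {
    lev <- sort(unique(labels))
    if (length(lev) != 2L) stop("labels must have exactly two levels")
    g1 <- labels == lev[1]
    n1 <- sum(g1); n2 <- sum(!g1)
    rk <- t(apply(nm, 1, rank))
    u <- rowSums(rk[, g1, drop = FALSE]) - n1 * (n1 + 1) / 2
    setNames(u / (n1 * n2), rownames(nm))
}

#' Call differentially expressed genes
#'
#' A gene is a DEG when \eqn{|log_2FC| \ge lfcMin} (default 1, i.e. at
#' least 2-fold) and FDR \eqn{\le fdrMax} (default 0.05); the direction is
#' the sign of the fold change, and genes are ranked within each direction
#' by AUROC distance from 0.5, descending.
#'
#' @param de data.frame from \code{\link{welchTests}} augmented with
#'   \code{fdr} and \code{auroc} columns.
#' @param lfcMin,fdrMax DEG thresholds (boundaries inclusive).
#' @return the data.frame with \code{is_deg}, \code{deg_direction}
#'   (\code{"up_c1"}, \code{"up_c2"} or \code{"none"}) and
#'   \code{deg_rank} (NA for non-DEGs) columns.
#' @export
callDEGs <- function(de, lfcMin = 1, fdrMax = 0.05) {
    stopifnot(all(c("fdr", "auroc") %in% names(de)))
    de$is_deg <- abs(de$log2fc) >= lfcMin & de$fdr <= fdrMax
    de$deg_direction <- ifelse(!de$is_deg, "none",
                        ifelse(de$log2fc > 0, "up_c1", "up_c2"))
    de$deg_rank <- NA_integer_
    for (dir in c("up_c1", "up_c2")) {
        idx <- which(de$deg_direction == dir)
        if (length(idx))
            de$deg_rank[idx] <- rank(-abs(de$auroc[idx] - 0.5),
                                     ties.method = "first")
    }
    de
}

#' Call Super DEGs
#'
#' The stringent subset of DEGs: mean expression of at least
#' \code{tpmMin} TPM in at least one cluster and at least a
#' \code{2^lfcMin}-fold difference (default: >= 10 TPM and >= 4-fold,
#' log2FC >= 2).  A DEG expressed below the TPM gate in both clusters --
#' such as a gene at 1.5 vs 0.0 TPM -- is excluded however extreme its
#' fold change.
#'
#' @param de DEG-called data.frame with \code{mean_tpm_c1},
#'   \code{mean_tpm_c2}.
#' @param tpmMin TPM gate (default 10).
#' @param lfcMin log2 fold-change gate (default 2).
#' @return the data.frame with an \code{is_super_deg} column.
#' @export
callSuperDEGs <- function(de, tpmMin = 10, lfcMin = 2) {
    stopifnot(all(c("is_deg", "mean_tpm_c1", "mean_tpm_c2") %in% names(de)))
    de$is_super_deg <- de$is_deg &
        pmax(de$mean_tpm_c1, de$mean_tpm_c2) >= tpmMin &
        abs(de$log2fc) >= lfcMin
    de
}

#' Call Cluster-similar genes
#'
#' Genes expressed at a level of at least \code{tpmMin} TPM in at least one
#' cluster that are \emph{not} DEGs and differ at most \code{2^lfcMax}-fold
#' between clusters (default: >= 10 TPM, <= 2-fold, log2FC <= 1).  DEGs are
#' excluded explicitly so the similarity and DEG sets cannot intersect.
#'
#' @param de DEG-called data.frame.
#' @param tpmMin TPM gate (default 10).
#' @param lfcMax log2 fold-change ceiling (default 1).
#' @return the data.frame with an \code{is_cluster_similar} column.
#' @export
callClusterSimilar <- function(de, tpmMin = 10, lfcMax = 1) {
    stopifnot(all(c("is_deg", "mean_tpm_c1", "mean_tpm_c2") %in% names(de)))
    de$is_cluster_similar <- !de$is_deg &
        pmax(de$mean_tpm_c1, de$mean_tpm_c2) >= tpmMin &
        abs(de$log2fc) <= lfcMax
    de
}

#' Kernel-density overlapping index
#'
#' Quantifies the similarity of two empirical distributions as the integral
#' of the pointwise minimum of their kernel density estimates: OI = 0 means
#' no overlap, OI = 1 perfect overlap.  Gaussian kernels with Silverman's
#' bandwidth per sample are evaluated on a shared uniform grid spanning the
#' pooled range plus three maximal bandwidths on either side; each density
#' is renormalized to integrate to one on the grid, so a sample compared
#' with itself gives exactly 1.  Samples with fewer than two distinct
#' values are treated as point masses and compared by equality.
#'
#' @param a,b numeric samples (non-empty).
#' @param nGrid grid points (minimum 1024).
#' @return OI in [0, 1].
#' @examples
#' x <- rnorm(500)
#' overlappingIndex(x, x)            # 1
#' overlappingIndex(x, x + 100)      # ~0
#' @export
overlappingIndex <- function(a, b, nGrid = 1024) {
    if (!length(a) || !length(b)) stop("samples must be non-empty")
    nGrid <- max(nGrid, 1024L)
    degA <- length(unique(a)) < 2L
    degB <- length(unique(b)) < 2L
    if (degA && degB) return(as.numeric(a[1] == b[1]))
    if (degA || degB) {
        pt <- if (degA) a[1] else b[1]
        smp <- if (degA) b else a
        bw <- bw.nrd0(smp)
        f <- density(smp, bw = bw, n = nGrid,
                     from = min(smp, pt) - 3 * bw,
                     to = max(smp, pt) + 3 * bw)
        # fraction of the continuous density attributable to the point mass
        return(min(1, f$y[which.min(abs(f$x - pt))] *
                       (f$x[2] - f$x[1])))
    }
    bwA <- bw.nrd0(a); bwB <- bw.nrd0(b)
    pad <- 3 * max(bwA, bwB)
    lo <- min(a, b) - pad; hi <- max(a, b) + pad
    fa <- density(a, bw = bwA, from = lo, to = hi, n = nGrid)
    fb <- density(b, bw = bwB, from = lo, to = hi, n = nGrid)
    dx <- fa$x[2] - fa$x[1]
    ya <- fa$y / sum(fa$y * dx)
    yb <- fb$y / sum(fb$y * dx)
    sum(pmin(ya, yb) * dx)
}

#' Rank Cluster-similar genes by distribution overlap
#'
#' For each similarity-flagged gene the overlapping index is computed
#' between the per-cell TPM distributions of the two clusters (zeros
#' included), genes are ranked by OI descending, and a high-stringency
#' subset is marked at \code{oiMin} (default 0.8).  Per-cluster mean TPM
#' and coefficients of variation accompany the table (balloon-plot data).
#'
#' @param de data.frame with \code{is_cluster_similar}.
#' @param tpm genes x cells TPM matrix.
#' @param labels two-level cluster labels.
#' @param oiMin high-stringency OI threshold.
#' @return data.frame of similar genes sorted by decreasing OI with
#'   \code{oi}, \code{oi_rank}, \code{high_stringency}, per-cluster mean
#'   TPM and CV.
#' @export
rankSimilarity <- function(de, tpm, labels, oiMin = 0.8) {
    stopifnot("is_cluster_similar" %in% names(de))
    lev <- sort(unique(labels))
    genes <- de$gene[de$is_cluster_similar]
    genes <- intersect(genes, rownames(tpm))
    if (!length(genes))
        return(data.frame(gene = character(0), oi = numeric(0),
                          oi_rank = integer(0),
                          high_stringency = logical(0)))
    g1 <- labels == lev[1]; g2 <- labels == lev[2]
    cv <- function(x) if (mean(x) > 0) sd(x) / mean(x) else NA_real_
    oi <- vapply(genes, function(g)
        overlappingIndex(tpm[g, g1], tpm[g, g2]), numeric(1))
    out <- data.frame(
        gene = genes, oi = oi,
        mean_tpm_c1 = rowMeans(tpm[genes, g1, drop = FALSE]),
        mean_tpm_c2 = rowMeans(tpm[genes, g2, drop = FALSE]),
        cv_c1 = apply(tpm[genes, g1, drop = FALSE], 1, cv),
        cv_c2 = apply(tpm[genes, g2, drop = FALSE], 1, cv))
    out <- out[order(-out$oi, out$gene), ]
    out$oi_rank <- seq_len(nrow(out))
    out$high_stringency <- out$oi >= oiMin
    rownames(out) <- out$gene
    out
}

#' Genes above an expression threshold in both or one cluster
#'
#' Splits genes by cluster-mean TPM relative to a threshold (the global
#' expression-profile comparison uses 1000 TPM): the intersection expressed
#' in both clusters versus the exclusive sets.
#'
#' @param meanTpmC1,meanTpmC2 named per-gene cluster means.
#' @param threshold TPM cutoff (> 0; default 1000).
#' @return list with \code{intersection}, \code{exclusive_c1},
#'   \code{exclusive_c2} gene-id vectors.
#' @export
expressionIntersection <- function(meanTpmC1, meanTpmC2,
                                   threshold = 1000) {
    if (threshold <= 0) stop("threshold must be positive")
    g <- names(meanTpmC1)
    a <- meanTpmC1 >= threshold
    b <- meanTpmC2 >= threshold
    list(intersection = g[a & b],
         exclusive_c1 = g[a & !b],
         exclusive_c2 = g[!a & b])
}

#' Full two-cluster differential expression analysis
#'
#' Runs the complete per-gene contrast: Welch t-tests on normalized log2
#' values, BH adjustment, AUROC ranking, cluster-mean TPM and percent
#' expressing, DEG / Super DEG / Cluster-similarity calls, and the
#' overlapping index for the similar genes.
#'
#' @param nm genes x cells normalized log2 matrix.
#' @param tpm genes x cells TPM matrix (same genes).
#' @param labels two-level cluster labels.
#' @param tpmExpressed TPM threshold for "percent expressing" (default 1).
#' @param ... thresholds passed to the calling functions.
#' @return data.frame, one row per gene, volcano-ready (log2fc, fdr,
#'   auroc, flags, OI where similarity-gated).
#' @export
differentialExpression <- function(nm, tpm, labels, tpmExpressed = 1,
                                   ...) {
    stopifnot(identical(rownames(nm), rownames(tpm)))
    lev <- sort(unique(labels))
    de <- welchTests(nm, labels)
    de$fdr <- bhAdjust(de$p_value)
    de$auroc <- aurocScores(nm, labels)
    g1 <- labels == lev[1]; g2 <- labels == lev[2]
    de$mean_tpm_c1 <- rowMeans(tpm[, g1, drop = FALSE])
    de$mean_tpm_c2 <- rowMeans(tpm[, g2, drop = FALSE])
    de$pct_c1 <- 100 * rowMeans(tpm[, g1, drop = FALSE] >= tpmExpressed)
    de$pct_c2 <- 100 * rowMeans(tpm[, g2, drop = FALSE] >= tpmExpressed)
    de <- callDEGs(de, ...)
    de <- callSuperDEGs(de)
    de <- callClusterSimilar(de)
    sim <- rankSimilarity(de, tpm, labels)
    de$oi <- NA_real_
    de$oi[match(sim$gene, de$gene)] <- sim$oi
    de
}
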