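#' @importFrom stats ks.test t.test wilcox.test complete.cases
NULL

#' PCA of electrophysiological features
#'
#' Z-scores the feature matrix (constant features are dropped with a
#' warning; missing values are mean-imputed for the embedding only, with a
#' message), runs centered PCA, fixes component signs by forcing the
#' largest-magnitude loading of each component positive, and reports PC1
#' loading scores ordered by magnitude plus the correlation of every
#' feature with PC1 and PC2 (vector factor map data).
#'
#' @param features data.frame or matrix of cells x features.
#' @param featureCols columns to use (default
#'   \code{\link{ephysFeatureNames}}).
#' @return list with \code{scores}, \code{varExplained},
#'   \code{loadings} (features x PCs), \code{pc1Loadings} (ordered by
#'   |loading|), \code{featureCor} (feature vs PC1/PC2 correlations),
#'   \code{imputed} (count of imputed entries).
#' @export
ephysPCA <- function(features, featureCols = ephysFeatureNames()) {
    featureCols <- intersect(featureCols, colnames(features))
    m <- as.matrix(as.data.frame(features)[, featureCols])
    mode(m) <- "numeric"
    keep <- apply(m, 2, function(x) {
        x <- x[!is.na(x)]
        length(x) > 1 && sd(x) > 0
    })
    if (!all(keep)) {
        warning("dropping constant/empty features: ",
                paste(featureCols[!keep], collapse = ", "))
        m <- m[, keep, drop = FALSE]
    }
    nImp <- sum(is.na(m))
    if (nImp > 0) {
        message(nImp, " missing entries mean-imputed for the embedding")
        for (j in seq_len(ncol(m)))
            m[is.na(m[, j]), j] <- mean(m[, j], na.rm = TRUE)
    }
    if (nrow(m) < ncol(m) + 1L)
        warning("fewer cells than features + 1: PCA under-determined")
    z <- scale(m)
    pc <- prcomp(z, center = FALSE)
    for (j in seq_len(ncol(pc$rotation))) {
        imax <- which.max(abs(pc$rotation[, j]))
        if (pc$rotation[imax, j] < 0) {
            pc$rotation[, j] <- -pc$rotation[, j]
            pc$x[, j] <- -pc$x[, j]
        }
    }
    varExp <- pc$sdev^2 / sum(pc$sdev^2)
    l1 <- pc$rotation[, 1]
    pc1Loadings <- data.frame(feature = names(l1), loading = l1)
    pc1Loadings <- pc1Loadings[order(-abs(pc1Loadings$loading)), ]
    rownames(pc1Loadings) <- NULL
    featureCor <- t(cor(z, pc$x[, seq_len(min(2L, ncol(pc$x))),
                                drop = FALSE]))
    list(scores = pc$x, varExplained = varExp,
         loadings = pc$rotation, pc1Loadings = pc1Loadings,
         featureCor = featureCor, imputed = nImp)
}

.sidak <- function(p, m) 1 - (1 - p)^m

#' Per-feature cohort statistics with the normality-gated test ladder
#'
#' For every feature and pairwise cohort comparison: a Kolmogorov--Smirnov
#' normality check of each cohort against its fitted normal (alpha = 0.05);
#' if both cohorts pass, a two-sample t-test, otherwise a Mann--Whitney U
#' test.  P-values are Sidak-corrected within a family of all pairwise
#' cohort comparisons of the same feature.  Missing values are dropped per
#' comparison, never imputed.
#'
#' @param features cells x features data.frame.
#' @param cohortLabels per-cell cohort labels (3 or more cells each).
#' @param featureCols feature columns (default the 16-feature set).
#' @param alpha significance level applied to the corrected p.
#' @return data.frame: feature, cohort_a, cohort_b, test, p_raw,
#'   p_corrected, significant.
#' @export
cohortStats <- function(features, cohortLabels,
                        featureCols = ephysFeatureNames(),
                        alpha = 0.05) {
    featureCols <- intersect(featureCols, colnames(features))
    lev <- sort(unique(cohortLabels))
    pairs <- combn(lev, 2, simplify = FALSE)
    m <- length(pairs)
    rows <- list()
    for (f in featureCols) {
        x <- as.numeric(features[[f]])
        for (pr in pairs) {
            a <- x[cohortLabels == pr[1]]; a <- a[!is.na(a)]
            b <- x[cohortLabels == pr[2]]; b <- b[!is.na(b)]
            if (length(a) < 3L || length(b) < 3L) {
                rows[[length(rows) + 1L]] <- data.frame(
                    feature = f, cohort_a = pr[1], cohort_b = pr[2],
                    test = NA_character_, p_raw = NA_real_,
                    p_corrected = NA_real_, significant = NA)
                next
            }
            normA <- length(unique(a)) > 1 &&
                suppressWarnings(ks.test(a, "pnorm", mean(a),
                                         sd(a))$p.value) > 0.05
            normB <- length(unique(b)) > 1 &&
                suppressWarnings(ks.test(b, "pnorm", mean(b),
                                         sd(b))$p.value) > 0.05
            if (normA && normB) {
                p <- t.test(a, b)$p.value
                test <- "t"
            } else {
                p <- suppressWarnings(wilcox.test(a, b)$p.value)
                test <- "mann-whitney"
            }
            rows[[length(rows) + 1L]] <- data.frame(
                feature = f, cohort_a = pr[1], cohort_b = pr[2],
                test = test, p_raw = p,
                p_corrected = min(1, .sidak(p, m)),
                significant = .sidak(p, m) <= alpha)
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Congruence between transcriptomic clusters and firing classes
#'
#' Tests the expected mapping ({Onset, Sustained} to one cluster, Delayed
#' to the other) in both orientations and keeps the one maximizing
#' matches.  Full congruence (fraction 1.0) means the physiology predicts
#' the transcriptomic cluster of every neuron.
#'
#' @param clusters per-cell transcriptomic cluster labels (two levels).
#' @param firingClasses per-cell classes (Onset/Sustained/Delayed).
#' @return list with \code{fraction} congruent, \code{ari}
#'   (chance-adjusted agreement) and the \code{table} contingency.
#' @export
congruence <- function(clusters, firingClasses) {
    if (length(clusters) != length(firingClasses))
        stop("label vectors must have equal length")
    lev <- sort(unique(clusters))
    if (length(lev) != 2L) stop("expected two transcriptomic clusters")
    pred1 <- ifelse(firingClasses == "Delayed", lev[2], lev[1])
    pred2 <- ifelse(firingClasses == "Delayed", lev[1], lev[2])
    f1 <- mean(pred1 == clusters)
    f2 <- mean(pred2 == clusters)
    list(fraction = max(f1, f2),
         ari = mclust::adjustedRandIndex(clusters, firingClasses == "Delayed"),
         table = table(cluster = clusters, class = firingClasses))
}

#' Annotate an embedding with firing classes
#'
#' @param embedding cells x 2 coordinate matrix with cell-id rownames.
#' @param classes named per-cell class labels (names = cell ids).
#' @return data.frame cell, dim1, dim2, firing_class.
#' @export
overlayEmbedding <- function(embedding, classes) {
    ids <- rownames(embedding)
    if (is.null(ids)) stop("embedding needs cell-id rownames")
    if (!all(ids %in% names(classes)))
        stop("unknown cell ids in embedding: ",
             paste(setdiff(ids, names(classes)), collapse = ", "))
    data.frame(cell = ids, dim1 = embedding[, 1], dim2 = embedding[, 2],
               firing_class = unname(classes[ids]),
               row.names = ids)
}
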