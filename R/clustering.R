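#' @importFrom stats kmeans hclust cutree dist cor prcomp cmdscale
#' @importFrom utils head combn
NULL

# cell-cell distance matrices over a genes x cells expression block
.cellDistances <- function(x) {
    list(
        euclidean = as.matrix(dist(t(x))),
        pearson = 1 - cor(x, method = "pearson"),
        spearman = 1 - cor(x, method = "spearman"))
}

# leading components of the (column-centered) distance matrix
.spectralEmbed <- function(dm, dmax) {
    pc <- prcomp(dm, center = TRUE, scale. = FALSE)
    pc$x[, seq_len(min(dmax, ncol(pc$x))), drop = FALSE]
}

#' Consensus clustering with silhouette-based model selection
#'
#' For each candidate cluster count k, an ensemble of k-means runs is
#' executed over three cell-cell distance measures (Euclidean, Pearson,
#' Spearman) crossed with a range of spectral dimensions d (the leading
#' eigenvectors of each distance matrix; d from \code{ceiling(0.04 n)} to
#' \code{ceiling(0.07 n)}).  The consensus matrix is the fraction of
#' ensemble members co-assigning each cell pair; final labels are an
#' average-linkage hierarchical cut of \code{1 - consensus} into k
#' clusters, and the average silhouette width is computed on the same
#' consensus-derived distances so the selection criterion matches the
#' construction.
#'
#' @param x genes x cells matrix of normalized log2 expression restricted
#'   to highly variable genes.
#' @param kRange candidate cluster counts (default 2:10).
#' @param nstart k-means restarts per ensemble member.
#' @param seed RNG seed for the ensemble.
#' @return a \linkS4class{ConsensusResult}; silhouette widths are \code{NA}
#'   for degenerate k.
#' @export
consensusCluster <- function(x, kRange = 2:10, nstart = 10, seed = 0) {
    n <- ncol(x)
    if (any(kRange >= n))
        stop("kRange must stay below the number of cells")
    if (n < max(kRange) + 2L)
        stop("need at least max(kRange) + 2 cells")
    set.seed(seed)
    dists <- .cellDistances(x)
    dRange <- seq.int(max(1L, ceiling(0.04 * n)),
                      max(1L, ceiling(0.07 * n)))
    embeds <- list()
    for (dn in names(dists))
        embeds[[dn]] <- .spectralEmbed(dists[[dn]], max(dRange))

    consensus <- list()
    sil <- setNames(rep(NA_real_, length(kRange)), kRange)
    labelsByK <- list()
    for (k in kRange) {
        co <- matrix(0, n, n)
        runs <- 0L
        for (dn in names(embeds)) {
            for (d in dRange) {
                emb <- embeds[[dn]][, seq_len(d), drop = FALSE]
                cl <- kmeans(emb, centers = k, nstart = nstart,
                             iter.max = 100)$cluster
                co <- co + outer(cl, cl, "==")
                runs <- runs + 1L
            }
        }
        co <- co / runs
        dimnames(co) <- list(colnames(x), colnames(x))
        consensus[[as.character(k)]] <- co
        dcons <- stats::as.dist(1 - co)
        lab <- cutree(hclust(dcons, method = "average"), k)
        labelsByK[[as.character(k)]] <- lab
        if (length(unique(lab)) > 1L) {
            sw <- cluster::silhouette(lab, dcons)
            sil[as.character(k)] <- mean(sw[, "sil_width"])
        }
    }
    kSel <- selectK(sil)
    new("ConsensusResult", consensus = consensus,
        labels = unname(labelsByK[[as.character(kSel)]]),
        silhouette = sil, kSelected = as.integer(kSel),
        method = "consensus")
}

#' Cut a consensus matrix into k clusters
#'
#' Average-linkage hierarchical cut of \code{1 - consensus} -- the same
#' rule that produces the selected labels -- at an arbitrary k, e.g. to
#' obtain the two-cluster partition when the silhouette selected another k.
#'
#' @param x a \linkS4class{ConsensusResult}.
#' @param k cluster count (must have a consensus matrix).
#' @return integer labels.
#' @export
consensusLabelsAt <- function(x, k) {
    cm <- consensusMatrix(x, k)
    if (is.null(cm)) stop("no consensus matrix for k = ", k)
    unname(cutree(hclust(stats::as.dist(1 - cm), method = "average"), k))
}

#' Choose the cluster count by average silhouette width
#'
#' Argmax of the average silhouette width over k; ties break toward the
#' smaller k.
#'
#' @param silhouetteByK named numeric vector, names are k values.
#' @return the selected k (integer).
#' @examples
#' selectK(c(`2` = 0.98, `3` = 0.4))
#' @export
selectK <- function(silhouetteByK) {
    ok <- !is.na(silhouetteByK)
    if (!any(ok)) stop("all silhouette widths undefined")
    s <- silhouetteByK[ok]
    ks <- as.integer(names(s))
    best <- which(s == max(s))
    as.integer(min(ks[best]))
}

#' Graph-based clustering
#'
#' A shared k-nearest-neighbour graph on the top principal components of
#' the expression block, partitioned by modularity (Louvain) community
#' detection.  Serves as the independent second method for cross-checking
#' the consensus labels.
#'
#' @param x genes x cells matrix (HVG-restricted logcounts).
#' @param kNN neighbours per cell (default 15, clipped below cell count).
#' @param nPCs principal components used (default 10).
#' @param seed RNG seed.
#' @return integer cluster labels, one per cell.
#' @export
graphCluster <- function(x, kNN = 15, nPCs = 10, seed = 0) {
    n <- ncol(x)
    if (n < 10L) stop("graph clustering needs at least 10 cells")
    set.seed(seed)
    pc <- prcomp(t(x), center = TRUE)
    nPCs <- min(nPCs, ncol(pc$x))
    sc <- pc$x[, seq_len(nPCs), drop = FALSE]
    dm <- as.matrix(dist(sc))
    kNN <- min(kNN, n - 1L)
    edges <- do.call(rbind, lapply(seq_len(n), function(i) {
        nb <- order(dm[i, ])[2:(kNN + 1L)]
        cbind(i, nb)
    }))
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::simplify(g)
    comm <- igraph::cluster_louvain(g)
    as.integer(igraph::membership(comm))
}

# best-matching cluster correspondence; exhaustive for small k, else greedy
.matchClusters <- function(tab) {
    ka <- nrow(tab); kb <- ncol(tab)
    if (ka <= kb && ka <= 6L) {
        perms <- .permutations(seq_len(kb))
        best <- 0; bestMap <- NULL
        for (p in perms) {
            ov <- sum(vapply(seq_len(ka),
                             function(i) tab[i, p[i]], numeric(1)))
            if (ov > best) { best <- ov; bestMap <- p[seq_len(ka)] }
        }
        vapply(seq_len(ka), function(i) tab[i, bestMap[i]], numeric(1))
    } else {
        t2 <- tab
        ov <- numeric(min(ka, kb))
        for (j in seq_along(ov)) {
            w <- which(t2 == max(t2), arr.ind = TRUE)[1, ]
            ov[j] <- t2[w[1], w[2]]
            t2[w[1], ] <- -1; t2[, w[2]] <- -1
        }
        ov
    }
}

.permutations <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
        for (rest in .permutations(v[-i]))
            out[[length(out) + 1L]] <- c(v[i], rest)
    out
}

#' Agreement between two clusterings
#'
#' @param a,b label vectors over the same cells.
#' @return list with the contingency \code{table}, the chance-adjusted
#'   agreement index \code{ari} (adjusted Rand; 1 iff the labelings are
#'   identical up to renaming), and \code{overlap}, the per-cluster
#'   maximal-matching overlap counts.
#' @examples
#' clusterAgreement(c(1, 1, 2, 2), c(2, 2, 1, 1))$ari
#' @export
clusterAgreement <- function(a, b) {
    if (length(a) != length(b))
        stop("label vectors must have equal length")
    tab <- table(a, b)
    list(table = tab,
         ari = mclust::adjustedRandIndex(a, b),
         overlap = .matchClusters(unclass(tab)))
}

#' PCA embedding of cells
#'
#' Centered principal component analysis of cells over the supplied genes.
#'
#' @param x genes x cells matrix.
#' @param nComponents components to retain.
#' @return list with \code{scores} (cells x components), \code{loadings}
#'   and \code{varExplained} (fraction of total variance per component).
#' @export
pcaEmbed <- function(x, nComponents = 10) {
    nComponents <- min(nComponents, ncol(x), nrow(x))
    pc <- prcomp(t(x), center = TRUE)
    keep <- seq_len(min(nComponents, ncol(pc$x)))
    list(scores = pc$x[, keep, drop = FALSE],
         loadings = pc$rotation[, keep, drop = FALSE],
         varExplained = (pc$sdev^2 / sum(pc$sdev^2))[keep])
}

#' Two-dimensional visualization embedding
#'
#' Deterministic 2-D embedding for plotting: classical multidimensional
#' scaling of the cell-cell distances over the top principal components
#' (default PC1--PC10).  Used for visualization only; cluster membership is
#' decided by \code{\link{consensusCluster}} / \code{\link{graphCluster}}.
#'
#' @param scores cells x components PCA score matrix (see
#'   \code{\link{pcaEmbed}}).
#' @param nPCs components entering the distance (default 10).
#' @return cells x 2 coordinate matrix with the input rownames.
#' @export
embed2D <- function(scores, nPCs = 10) {
    nPCs <- min(nPCs, ncol(scores))
    xy <- cmdscale(dist(scores[, seq_len(nPCs), drop = FALSE]), k = 2)
    colnames(xy) <- c("dim1", "dim2")
    xy
}
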