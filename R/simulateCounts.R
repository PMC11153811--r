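#' @importFrom stats rnorm rlnorm rnbinom rpois runif rbinom qexp pexp
#'   rexp median mad quantile setNames
NULL

# truncated normal by clamping (simple, adequate for parameter realizations)
.rnormClamp <- function(n, mean, sd, lo = -Inf, hi = Inf)
    pmin(pmax(rnorm(n, mean, sd), lo), hi)

.drawLatency <- function(law, n) {
    if (identical(law$type, "lognormal")) {
        rlnorm(n, law$meanlog, law$sdlog)
    } else if (identical(law$type, "shiftedexp")) {
        # inverse-CDF truncation keeps support within [shift, max]
        u <- runif(n) * pexp(law$max - law$shift, rate = 1 / law$scale)
        law$shift + qexp(u, rate = 1 / law$scale)
    } else stop("unknown latency law: ", law$type)
}

# Effective sag amplitude |V_min - V_ss| of the noiseless -200 pA response:
# the planted slow component rides on the residual RC relaxation, so the
# measurable sag differs slightly from the raw component amplitude.
.sagEffective <- function(rIn, cM, sagComp, tauSag, amp = -200,
                          stepMs = 200) {
    if (sagComp <= 0) return(0)
    tauM <- rIn * cM / 1000                     # ms
    t <- seq(0, stepMs, by = 0.02)
    dV <- abs(amp) * rIn / 1000                 # mV
    w <- (1 - exp(-t / tauM)) * exp(-t / tauSag)
    w <- w / max(w)
    v <- -dV * (1 - exp(-t / tauM)) - sagComp * w
    ss <- mean(v[t >= 0.75 * stepMs])
    ss - min(v)
}

.drawTrueEphys <- function(config, classes) {
    n <- length(classes)
    cols <- c("vRest", "rIn", "cM", "tauM", "rS", "rheobase", "latency",
              "sagComponent", "sag", "reboundAmp")
    df <- as.data.frame(setNames(
        lapply(cols, function(x) rep(NA_real_, n)), cols))
    df$class <- classes
    for (cl in c("Onset", "Sustained", "Delayed")) {
        idx <- which(classes == cl)
        if (!length(idx)) next
        p <- config@ephysParams[[cl]]
        m <- length(idx)
        df$vRest[idx] <- rnorm(m, p$vRest$mean, p$vRest$sd)
        df$rIn[idx] <- .rnormClamp(m, p$rIn$mean, p$rIn$sd,
                                   lo = 0.5 * p$rIn$mean)
        df$cM[idx] <- .rnormClamp(m, p$cM$mean, p$cM$sd, lo = 0.5 * p$cM$mean)
        df$rS[idx] <- p$rS
        df$rheobase[idx] <- .rnormClamp(m, p$rheobase$mean, p$rheobase$sd,
                                        p$rheobase$min, p$rheobase$max)
        df$latency[idx] <- .drawLatency(p$latency, m)
        df$sagComponent[idx] <-
            if (p$sag$mean > 0)
                .rnormClamp(m, p$sag$mean, p$sag$sd, lo = p$sag$min) else 0
        df$reboundAmp[idx] <- p$rebound$amp
        df$tauM[idx] <- df$rIn[idx] * df$cM[idx] / 1000
        df$sag[idx] <- vapply(idx, function(i)
            .sagEffective(df$rIn[i], df$cM[i], df$sagComponent[i],
                          p$tauSag), numeric(1))
    }
    df
}

#' Simulate a patch-seq count matrix with ground truth
#'
#' Draws a genes x cells integer count matrix with the generative structure
#' assumed by the analysis: negative-binomial counts with log-normal per-gene
#' baselines, planted up-regulated markers in each of the two transcriptomic
#' clusters (cluster 1 = Onset + Sustained pLSO neurons, cluster 2 = Delayed
#' LOC neurons), a block of highly expressed housekeeping genes shared by
#' both clusters, Bernoulli-gated neurotransmitter-panel genes with
#' class-specific expression probabilities, log-normal library-size
#' variation, negative-control libraries at \code{depthScale} (default 1/8)
#' of neuronal depth, and independent dropout zeroing.  The per-cell
#' electrophysiological parameter realizations used later by
#' \code{\link{simulateTraces}} are drawn here so that the returned
#' \linkS4class{GroundTruth} describes the complete paired dataset.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param seed integer seed (default \code{config@seed}); the same seed
#'   reproduces the dataset exactly.
#' @return A list with elements \code{sce} (a
#'   \link[SingleCellExperiment]{SingleCellExperiment} with assay
#'   \code{"counts"} and gene lengths in \code{rowData}) and \code{truth}
#'   (a \linkS4class{GroundTruth}).
#' @examples
#' sim <- simulateCounts(simConfig(nGenes = 300, nMarkersC1 = 30,
#'                                 nMarkersC2 = 15))
#' sim$sce
#' sim$truth
#' @export
simulateCounts <- function(config, seed = config@seed) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    set.seed(seed)

    nNeuron <- config@nOnset + config@nSustained + config@nDelayed
    nCell <- nNeuron + config@negcontrolN
    classes <- c(rep("Onset", config@nOnset),
                 rep("Sustained", config@nSustained),
                 rep("Delayed", config@nDelayed),
                 rep("NegControl", config@negcontrolN))
    cluster <- ifelse(classes == "Delayed", 2L,
               ifelse(classes == "NegControl", NA_integer_, 1L))
    cellIds <- sprintf("cell_%03d", seq_len(nCell))

    nt <- nrow(config@transmitterProbs)
    hk <- config@housekeeping$n
    nG <- config@nGenes
    iC1 <- seq_len(config@nMarkersC1)
    iC2 <- seq_len(config@nMarkersC2) + config@nMarkersC1
    iHK <- seq_len(hk) + config@nMarkersC1 + config@nMarkersC2
    iNT <- seq_len(nt) + config@nMarkersC1 + config@nMarkersC2 + hk
    geneIds <- sprintf("gene%04d", seq_len(nG))
    geneIds[iNT] <- rownames(config@transmitterProbs)

    geneLength <- as.integer(round(runif(nG, config@geneLengthRange[1],
                                         config@geneLengthRange[2])))

    base <- rlnorm(nG, config@baselineLaw$meanlog, config@baselineLaw$sdlog)
    base[iHK] <- rlnorm(hk, config@housekeeping$meanlog,
                        config@housekeeping$sdlog)
    base[iNT] <- 0   # panel genes are fully gate-driven

    deFlag <- rep("none", nG)
    deFlag[iC1] <- "up_c1"
    deFlag[iC2] <- "up_c2"
    lfc <- numeric(nG)
    law <- config@markerLog2FC
    if (length(iC1))
        lfc[iC1] <- law$offset + abs(rnorm(length(iC1), law$mean, law$sd))
    if (length(iC2))
        lfc[iC2] <- -(law$offset + abs(rnorm(length(iC2), law$mean, law$sd)))

    sf <- exp(rnorm(nCell, 0, config@libsizeLaw$sdlog))
    sf[classes == "NegControl"] <- sf[classes == "NegControl"] *
        config@depthScale

    # mean matrix: baseline scaled by size factor, markers boosted in their
    # target cluster (cluster NA controls keep the baseline)
    mu <- outer(base, sf)
    inC1 <- !is.na(cluster) & cluster == 1L
    inC2 <- !is.na(cluster) & cluster == 2L
    if (length(iC1))
        mu[iC1, inC1] <- mu[iC1, inC1] * 2 ^ (lfc[iC1])
    if (length(iC2))
        mu[iC2, inC2] <- mu[iC2, inC2] * 2 ^ (-lfc[iC2])

    counts <- matrix(0L, nG, nCell, dimnames = list(geneIds, cellIds))
    flat <- as.vector(mu)
    if (config@dispersion > 1e-8) {
        counts[] <- rnbinom(length(flat), mu = flat,
                            size = 1 / config@dispersion)
    } else {
        counts[] <- rpois(length(flat), flat)
    }

    # neurotransmitter panel: Bernoulli gate x NB magnitude
    probs <- config@transmitterProbs
    nWeights <- c(config@nOnset, config@nSustained, config@nDelayed)
    ctrlProb <- as.vector(probs %*% nWeights) / sum(nWeights)
    for (g in seq_len(nt)) {
        pCell <- rep(ctrlProb[g], nCell)
        neuron <- classes != "NegControl"
        pCell[neuron] <- probs[g, classes[neuron]]
        gate <- rbinom(nCell, 1, pCell)
        muNT <- gate * config@transmitterMean * sf
        counts[iNT[g], ] <- if (config@dispersion > 1e-8)
            rnbinom(nCell, mu = muNT, size = 1 / config@dispersion)
        else rpois(nCell, muNT)
    }

    if (config@dropoutRate > 0) {
        keepRows <- setdiff(seq_len(nG), iNT)
        drop <- matrix(rbinom(length(keepRows) * nCell, 1,
                              config@dropoutRate),
                       length(keepRows), nCell)
        counts[keepRows, ][drop == 1L] <- 0L
    }

    storage.mode(counts) <- "integer"

    trueEphys <- .drawTrueEphys(config, classes)
    trueEphys$cell <- cellIds
    rownames(trueEphys) <- cellIds

    truth <- new("GroundTruth", cellClass = classes, cluster = cluster,
                 geneDEFlag = deFlag, trueLog2FC = lfc,
                 baseMean = setNames(base, geneIds),
                 trueEphys = trueEphys, sizeFactor = setNames(sf, cellIds))

    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts),
        rowData = S4Vectors::DataFrame(gene_id = geneIds,
                                       length = geneLength,
                                       row.names = geneIds),
        colData = S4Vectors::DataFrame(cell_id = cellIds,
                                       row.names = cellIds))
    list(sce = sce, truth = truth)
}
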