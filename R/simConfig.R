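#' Per-class electrophysiological parameter defaults
#'
#' Default generative parameters for the three LSO firing classes.  Principal
#' LSO neurons (pLSO; Onset and Sustained firing) rest near -64 mV with an
#' input resistance of about 96 MOhm and a membrane capacitance of about
#' 11 pF; lateral olivocochlear neurons (LOC; Delayed firing) rest near
#' -43 mV with a much higher input resistance (~300 MOhm), smaller
#' capacitance (~6 pF), no voltage sag and slower synaptic kinetics.  First
#' action-potential latencies centre on 2.9 ms (Onset), 7.0 ms (Sustained)
#' and 29.4 ms with support 25--180 ms (Delayed).
#'
#' Fields per class: \code{vRest}, \code{rIn}, \code{cM} (mean/sd),
#' \code{rS} (MOhm), \code{rheobase} (mean/sd/min/max, pA), \code{latency}
#' (distribution law, ms), \code{sag} (mean/sd mV; amplitude of the slow opposing
#' component at -200 pA) with \code{tauSag} (ms), \code{rebound}
#' (amplitude mV, tau ms), \code{ap} (template peak mV, rise/fall ms, clip
#' voltage mV), \code{firing} (rule and rate parameters) and \code{psc}
#' (per-polarity rate Hz, amplitude pA, rise/decay ms, amplitude CV).
#'
#' @return Named list with elements \code{Onset}, \code{Sustained},
#'   \code{Delayed}.
#' @examples
#' ephysClassDefaults()$Delayed$vRest
#' @export
ephysClassDefaults <- function() {
    ap <- list(peak = 25, rise = 0.4, fall = 0.8, clip = -25)
    pscPLSO <- list(
        epsc = list(rate = 2, amp = 50, rise = 0.3, decay = 1.2, ampCV = 0.2),
        ipsc = list(rate = 2, amp = 60, rise = 0.5, decay = 3.0, ampCV = 0.2))
    pscLOC <- list(
        epsc = list(rate = 2, amp = 40, rise = 0.5, decay = 2.4, ampCV = 0.2),
        ipsc = list(rate = 2, amp = 45, rise = 0.8, decay = 6.0, ampCV = 0.2))
    list(
        Onset = list(
            vRest = list(mean = -64, sd = 2),
            rIn = list(mean = 96, sd = 10),
            cM = list(mean = 11, sd = 1),
            rS = 10,
            rheobase = list(mean = 250, sd = 30, min = 150, max = 400),
            latency = list(type = "lognormal", meanlog = log(2.9),
                           sdlog = 0.25),
            sag = list(mean = 4, sd = 1, min = 1.5),
            tauSag = 30,
            rebound = list(amp = 2, tau = 20),
            ap = ap,
            firing = list(rule = "onset", burstInterval = 5,
                          extraPer = 300, maxAPs = 3),
            psc = pscPLSO
        ),
        Sustained = list(
            vRest = list(mean = -64, sd = 2),
            rIn = list(mean = 96, sd = 10),
            cM = list(mean = 11, sd = 1),
            rS = 10,
            rheobase = list(mean = 200, sd = 30, min = 100, max = 350),
            latency = list(type = "lognormal", meanlog = log(7.0),
                           sdlog = 0.25),
            sag = list(mean = 4, sd = 1, min = 1.5),
            tauSag = 30,
            rebound = list(amp = 2, tau = 20),
            ap = ap,
            firing = list(rule = "sustained", rate0 = 10, gain = 0.25),
            psc = pscPLSO
        ),
        Delayed = list(
            vRest = list(mean = -43, sd = 2),
            rIn = list(mean = 300, sd = 30),
            cM = list(mean = 6, sd = 0.5),
            rS = 10,
            rheobase = list(mean = 75, sd = 20, min = 30, max = 140),
            latency = list(type = "shiftedexp", shift = 25, scale = 4.4,
                           max = 180),
            sag = list(mean = 0, sd = 0, min = 0),
            tauSag = 30,
            rebound = list(amp = 0, tau = 20),
            ap = ap,
            firing = list(rule = "delayed", rate0 = 20, gain = 0.05),
            psc = pscLOC
        )
    )
}

#' Default neurotransmitter-panel expression probabilities
#'
#' Per-class Bernoulli gate probabilities for the seven neurotransmitter-
#' associated genes (vGLUT2 = Slc17a6, GlyT2 = Slc6a5, GAD65 = Gad2, Ddc,
#' ChAT = Chat, CGRP = Calca, urocortin = Ucn).  Calibrated so that ~66\% of
#' pLSO cells express vGLUT2, 93\% / 83\% of LOC cells express CGRP /
#' urocortin, and the mean per-cell combination sizes are about 1.1
#' (pLSO-Onset), 1.6 (pLSO-Sustained) and 3.3 (LOC).
#'
#' @return 7 x 3 numeric matrix, rows = gene symbols, columns =
#'   \code{Onset}, \code{Sustained}, \code{Delayed}.
#' @examples
#' colSums(transmitterProbDefaults())
#' @export
transmitterProbDefaults <- function() {
    m <- rbind(
        Slc17a6 = c(0.66, 0.66, 0.25),
        Slc6a5  = c(0.15, 0.30, 0.09),
        Gad2    = c(0.10, 0.20, 0.20),
        Ddc     = c(0.05, 0.12, 0.40),
        Chat    = c(0.05, 0.12, 0.60),
        Calca   = c(0.04, 0.10, 0.93),
        Ucn     = c(0.05, 0.10, 0.83))
    colnames(m) <- c("Onset", "Sustained", "Delayed")
    m
}

#' Simulation configuration
#'
#' Describes one synthetic patch-seq study: a genes x cells negative-binomial
#' count matrix with planted cluster markers, highly expressed housekeeping
#' genes, gated neurotransmitter-panel genes and shallow negative controls,
#' paired with parametric per-cell electrophysiology under the standard
#' stimulus protocols (current steps -200..1000 pA in 50-pA increments of
#' 200 ms, a -5 mV voltage-clamp step from -70 mV, a 30-s rest segment, a
#' 60-s PSC recording, triangular pulses).
#'
#' @slot nOnset,nSustained,nDelayed cell counts per firing class.
#' @slot nGenes total gene count.
#' @slot nMarkersC1,nMarkersC2 planted up-regulated markers per cluster.
#' @slot markerLog2FC law \code{offset + |Normal(mean, sd)|}.
#' @slot baselineLaw log-normal law for per-gene baseline means.
#' @slot housekeeping count and log-normal law of the shared high-expression
#'   block.
#' @slot dispersion NB dispersion (1/size) shared across genes.
#' @slot libsizeLaw log-normal law (sdlog) of per-cell size factors.
#' @slot negcontrolN,depthScale negative-control count and depth scaling.
#' @slot dropoutRate independent Bernoulli zeroing probability.
#' @slot geneLengthRange uniform integer range of gene lengths (bp).
#' @slot transmitterProbs 7 x 3 gate probability matrix.
#' @slot transmitterMean NB mean of a gated-on transmitter gene.
#' @slot ephysParams per-class parameter list, see
#'   \code{\link{ephysClassDefaults}}.
#' @slot noiseSD additive noise (voltage mV, current pA).
#' @slot samplingRates Hz per protocol (step, vc, psc, rest, triangle).
#' @slot stepRange,stepIncrement,stepDuration current-step family (pA, s).
#' @slot restDuration,pscDuration seconds.
#' @slot seed integer default seed.
#'
#' @exportClass SimConfig
setClass("SimConfig",
    representation(
        nOnset = "integer", nSustained = "integer", nDelayed = "integer",
        nGenes = "integer", nMarkersC1 = "integer", nMarkersC2 = "integer",
        markerLog2FC = "list", baselineLaw = "list", housekeeping = "list",
        dispersion = "numeric", libsizeLaw = "list",
        negcontrolN = "integer", depthScale = "numeric",
        dropoutRate = "numeric", geneLengthRange = "numeric",
        transmitterProbs = "matrix", transmitterMean = "numeric",
        ephysParams = "list", noiseSD = "list", samplingRates = "list",
        stepRange = "numeric", stepIncrement = "numeric",
        stepDuration = "numeric", restDuration = "numeric",
        pscDuration = "numeric", seed = "integer"
    )
)

setValidity("SimConfig", function(object) {
    msg <- NULL
    cnt <- c(object@nOnset, object@nSustained, object@nDelayed,
             object@nGenes, object@nMarkersC1, object@nMarkersC2,
             object@negcontrolN)
    if (any(cnt < 0)) msg <- c(msg, "all counts must be >= 0")
    nReserved <- object@housekeeping$n + nrow(object@transmitterProbs)
    if (object@nMarkersC1 + object@nMarkersC2 > object@nGenes - nReserved)
        msg <- c(msg, "marker genes exceed available (non-reserved) genes")
    if (object@depthScale <= 0 || object@depthScale >= 1)
        msg <- c(msg, "depthScale must be in (0,1)")
    if (object@dropoutRate < 0 || object@dropoutRate > 1)
        msg <- c(msg, "dropoutRate must be a probability")
    if (any(object@transmitterProbs < 0 | object@transmitterProbs > 1))
        msg <- c(msg, "transmitterProbs must be probabilities")
    for (cl in names(object@ephysParams)) {
        p <- object@ephysParams[[cl]]
        tau <- p$rIn$mean * p$cM$mean / 1000    # MOhm * pF -> ms
        if (tau <= 0 || tau >= 50)
            msg <- c(msg, sprintf("%s: tau_m = rIn*cM must be in (0, 50) ms",
                                  cl))
        if (identical(p$latency$type, "shiftedexp") &&
            (p$latency$shift < 25 || p$latency$max > 180))
            msg <- c(msg, sprintf(
                "%s: delayed latency support must lie within [25, 180] ms",
                cl))
    }
    if (is.null(msg)) TRUE else msg
})

#' Create a simulation configuration
#'
#' All arguments have study defaults: 44 Onset + 12 Sustained (cluster 1,
#' pLSO) and 30 Delayed (cluster 2, LOC) neurons plus 4 negative controls at
#' 8-fold lower depth; 2000 genes of which 250 / 100 are planted cluster-1 /
#' cluster-2 markers with log2 fold changes 1 + |N(0.5, 0.5)|.
#'
#' @param nOnset,nSustained,nDelayed cells per firing class.
#' @param nGenes number of genes.
#' @param nMarkersC1,nMarkersC2 planted marker counts.
#' @param markerLog2FC list(offset, mean, sd).
#' @param baselineLaw list(meanlog, sdlog) for baseline NB means.
#' @param housekeeping list(n, meanlog, sdlog) of the shared block.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param libsizeLaw list(sdlog); size factors are exp(N(0, sdlog)).
#' @param negcontrolN number of negative-control libraries.
#' @param depthScale control depth relative to neurons (default 1/8).
#' @param dropoutRate independent zeroing probability (default 0.05).
#' @param geneLengthRange uniform integer gene-length range in bp.
#' @param transmitterProbs gate matrix, see
#'   \code{\link{transmitterProbDefaults}}.
#' @param transmitterMean NB mean of a gated-on panel gene.
#' @param ephysParams per-class list, see \code{\link{ephysClassDefaults}}.
#' @param noiseSD list(voltage, current) additive noise SDs.
#' @param samplingRates list(step, vc, psc, rest, triangle) in Hz.
#' @param stepRange,stepIncrement,stepDuration current-step protocol.
#' @param restDuration,pscDuration seconds of rest / PSC recording.
#' @param seed default RNG seed.
#' @return A validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(nGenes = 500, nMarkersC1 = 40, nMarkersC2 = 20)
#' cfg
#' @export
simConfig <- function(nOnset = 44, nSustained = 12, nDelayed = 30,
                      nGenes = 2000, nMarkersC1 = 250, nMarkersC2 = 100,
                      markerLog2FC = list(offset = 1, mean = 0.5, sd = 0.5),
                      baselineLaw = list(meanlog = 1, sdlog = 1.5),
                      housekeeping = list(n = 50, meanlog = log(500),
                                          sdlog = 0.5),
                      dispersion = 0.3,
                      libsizeLaw = list(sdlog = 0.3),
                      negcontrolN = 4, depthScale = 1 / 8,
                      dropoutRate = 0.05,
                      geneLengthRange = c(500, 5000),
                      transmitterProbs = transmitterProbDefaults(),
                      transmitterMean = 30,
                      ephysParams = ephysClassDefaults(),
                      noiseSD = list(voltage = 0.5, current = 3),
                      samplingRates = list(step = 50000, vc = 20000,
                                           psc = 20000, rest = 5000,
                                           triangle = 50000),
                      stepRange = c(-200, 1000), stepIncrement = 50,
                      stepDuration = 0.2,
                      restDuration = 30, pscDuration = 60,
                      seed = 1) {
    housekeeping$n <- as.integer(housekeeping$n)
    new("SimConfig",
        nOnset = as.integer(nOnset), nSustained = as.integer(nSustained),
        nDelayed = as.integer(nDelayed), nGenes = as.integer(nGenes),
        nMarkersC1 = as.integer(nMarkersC1),
        nMarkersC2 = as.integer(nMarkersC2),
        markerLog2FC = markerLog2FC, baselineLaw = baselineLaw,
        housekeeping = housekeeping, dispersion = dispersion,
        libsizeLaw = libsizeLaw, negcontrolN = as.integer(negcontrolN),
        depthScale = depthScale, dropoutRate = dropoutRate,
        geneLengthRange = geneLengthRange,
        transmitterProbs = transmitterProbs,
        transmitterMean = transmitterMean,
        ephysParams = ephysParams, noiseSD = noiseSD,
        samplingRates = samplingRates, stepRange = stepRange,
        stepIncrement = stepIncrement, stepDuration = stepDuration,
        restDuration = restDuration, pscDuration = pscDuration,
        seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
    cat(sprintf(paste0(
        "SimConfig: %d Onset + %d Sustained + %d Delayed neurons",
        " (+%d controls at 1/%g depth)\n"),
        object@nOnset, object@nSustained, object@nDelayed,
        object@negcontrolN, round(1 / object@depthScale)))
    cat(sprintf("  %d genes: %d up_c1 + %d up_c2 markers, %d housekeeping, %d panel\n",
        object@nGenes, object@nMarkersC1, object@nMarkersC2,
        object@housekeeping$n, nrow(object@transmitterProbs)))
    cat(sprintf("  dispersion %.2f, dropout %.2f, seed %d\n",
        object@dispersion, object@dropoutRate, object@seed))
})
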