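#' @import methods
#' @importFrom S4Vectors SimpleList metadata metadata<-
NULL

#' Single stimulus-tagged recording
#'
#' A \code{Trace} holds one sweep of an intracellular recording on a uniform
#' time grid: voltage (mV) for current-clamp protocols, current (pA) for
#' voltage-clamp protocols.  The time axis is implicit:
#' \code{t[i] = (i - 1) / samplingRate} seconds, with stimulus timing carried
#' in \code{stimParams} (\code{onset}, \code{offset}, \code{amp}, ...).
#'
#' @slot signal numeric vector of samples.
#' @slot samplingRate sampling frequency in Hz.
#' @slot units \code{"mV"} or \code{"pA"}.
#' @slot protocol protocol tag, one of \code{"rest"}, \code{"step"},
#'   \code{"triangle"}, \code{"vc_step"}, \code{"psc"}.
#' @slot stimParams named list of stimulus parameters (seconds / pA / mV).
#'
#' @exportClass Trace
setClass("Trace",
    representation(
        signal = "numeric",
        samplingRate = "numeric",
        units = "character",
        protocol = "character",
        stimParams = "list"
    )
)

setValidity("Trace", function(object) {
    msg <- NULL
    if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
        msg <- c(msg, "samplingRate must be a single positive number")
    if (length(object@units) != 1L || !object@units %in% c("mV", "pA"))
        msg <- c(msg, "units must be 'mV' or 'pA'")
    if (length(object@protocol) != 1L)
        msg <- c(msg, "protocol must be a single tag")
    cc <- c(rest = "mV", step = "mV", triangle = "mV",
            vc_step = "pA", psc = "pA")
    if (object@protocol %in% names(cc) && object@units != cc[[object@protocol]])
        msg <- c(msg, sprintf("protocol '%s' requires units '%s'",
                              object@protocol, cc[[object@protocol]]))
    if (is.null(msg)) TRUE else msg
})

#' Construct a Trace
#'
#' @param signal numeric samples.
#' @param samplingRate Hz.
#' @param units "mV" or "pA".
#' @param protocol protocol tag.
#' @param stimParams named list (e.g. \code{onset}, \code{offset} in seconds,
#'   \code{amp} in pA or mV).
#' @return A \linkS4class{Trace}.
#' @examples
#' tr <- Trace(rnorm(100, -64, 0.5), 5000, "mV", "rest")
#' traceTime(tr)[1:3]
#' @export
Trace <- function(signal, samplingRate, units, protocol, stimParams = list()) {
    new("Trace", signal = as.numeric(signal),
        samplingRate = as.numeric(samplingRate),
        units = units, protocol = protocol, stimParams = stimParams)
}

#' @describeIn Trace signal samples.
#' @param x,object a \code{Trace}.
#' @export
traceSignal <- function(x) x@signal

#' @describeIn Trace implicit time axis in seconds.
#' @export
traceTime <- function(x) (seq_along(x@signal) - 1L) / x@samplingRate

#' @describeIn Trace sampling rate in Hz.
#' @export
samplingRate <- function(x) x@samplingRate

#' @describeIn Trace units string.
#' @export
traceUnits <- function(x) x@units

#' @describeIn Trace protocol tag.
#' @export
traceProtocol <- function(x) x@protocol

#' @describeIn Trace stimulus parameter list.
#' @export
stimParams <- function(x) x@stimParams

setMethod("show", "Trace", function(object) {
    cat(sprintf("Trace [%s] %d samples @ %g kHz (%s)\n", object@protocol,
        length(object@signal), object@samplingRate / 1000, object@units))
    if (length(object@stimParams))
        cat("  stim:", paste(names(object@stimParams),
            vapply(object@stimParams, function(p)
                paste(format(unlist(p)[seq_len(min(3, length(unlist(p))))],
                             digits = 4), collapse = ","), ""),
            sep = "=", collapse = " "), "\n")
})

#' Traces belonging to one cell
#'
#' A named \code{SimpleList} of \linkS4class{Trace} objects; current-step
#' families use names \code{step_<amp>} (one per amplitude).
#'
#' @exportClass CellTraces
setClass("CellTraces", contains = "SimpleList",
         prototype = prototype(elementType = "Trace"))

#' @rdname CellTraces-class
#' @param ... named \code{Trace} objects.
#' @export
CellTraces <- function(...) {
    lst <- SimpleList(...)
    new("CellTraces", lst)
}

#' A collection of per-cell trace bundles
#'
#' Named \code{SimpleList} of \linkS4class{CellTraces}, one element per cell.
#'
#' @exportClass TraceSet
setClass("TraceSet", contains = "SimpleList",
         prototype = prototype(elementType = "CellTraces"))

#' @rdname TraceSet-class
#' @param ... named \code{CellTraces} objects (one per cell).
#' @export
TraceSet <- function(...) new("TraceSet", SimpleList(...))

setMethod("show", "TraceSet", function(object) {
    cat(sprintf("TraceSet with %d cells\n", length(object)))
    if (length(object)) {
        nm <- names(object)[seq_len(min(3L, length(object)))]
        for (n in nm)
            cat(sprintf("  %s: %s\n", n,
                paste(names(object[[n]]), collapse = ", ")))
        if (length(object) > 3L) cat("  ...\n")
    }
})

#' Extract the current-step sweep family of one cell
#'
#' @param ct a \linkS4class{CellTraces}.
#' @return list of step \code{Trace}s ordered by stimulus amplitude.
#' @export
stepFamily <- function(ct) {
    idx <- which(vapply(ct, function(t) t@protocol == "step", logical(1)))
    sw <- as.list(ct[idx])
    amps <- vapply(sw, function(t) t@stimParams$amp, numeric(1))
    sw[order(amps)]
}

#' Generator-side ground truth
#'
#' Container for everything the simulator planted: per-cell class and cluster
#' labels, per-gene differential-expression flags and true log2 fold changes,
#' the per-cell electrophysiological parameter realizations, and the per-cell
#' true library size factors.  Intended for recovery tests, not analysis.
#'
#' @slot cellClass character, one of Onset/Sustained/Delayed/NegControl.
#' @slot cluster integer 1 (Onset+Sustained), 2 (Delayed), NA (controls).
#' @slot geneDEFlag character, "none", "up_c1" or "up_c2" per gene.
#' @slot trueLog2FC numeric per gene, cluster1 minus cluster2 convention.
#' @slot baseMean numeric per gene, baseline NB mean before size scaling.
#' @slot trueEphys data.frame, one row per cell of planted parameters.
#' @slot sizeFactor numeric per cell, true library scaling.
#'
#' @exportClass GroundTruth
setClass("GroundTruth",
    representation(
        cellClass = "character",
        cluster = "integer",
        geneDEFlag = "character",
        trueLog2FC = "numeric",
        baseMean = "numeric",
        trueEphys = "data.frame",
        sizeFactor = "numeric"
    )
)

setValidity("GroundTruth", function(object) {
    msg <- NULL
    n <- length(object@cellClass)
    if (length(object@cluster) != n || length(object@sizeFactor) != n)
        msg <- c(msg, "per-cell slots must have equal length")
    if (length(object@geneDEFlag) != length(object@trueLog2FC))
        msg <- c(msg, "per-gene slots must have equal length")
    if (!all(object@cellClass %in%
             c("Onset", "Sustained", "Delayed", "NegControl")))
        msg <- c(msg, "unknown cell class")
    expected <- ifelse(object@cellClass == "Delayed", 2L,
                ifelse(object@cellClass == "NegControl", NA_integer_, 1L))
    if (!identical(object@cluster, expected))
        msg <- c(msg, "cluster must be a deterministic function of cellClass")
    if (any(object@trueLog2FC[object@geneDEFlag == "none"] != 0))
        msg <- c(msg, "non-DE genes must have trueLog2FC 0")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn GroundTruth per-cell class labels.
#' @param x,object a \code{GroundTruth}.
#' @export
cellClass <- function(x) x@cellClass

#' @describeIn GroundTruth per-cell true cluster (1, 2 or NA).
#' @export
trueCluster <- function(x) x@cluster

#' @describeIn GroundTruth per-gene DE flag.
#' @export
geneDEFlag <- function(x) x@geneDEFlag

#' @describeIn GroundTruth per-gene true log2 fold change (c1 - c2).
#' @export
trueLog2FC <- function(x) x@trueLog2FC

#' @describeIn GroundTruth per-gene baseline mean expression.
#' @export
trueBaseMean <- function(x) x@baseMean

#' @describeIn GroundTruth per-cell planted ephys parameters.
#' @export
trueEphys <- function(x) x@trueEphys

#' @describeIn GroundTruth per-cell true size factors.
#' @export
trueSizeFactor <- function(x) x@sizeFactor

setMethod("show", "GroundTruth", function(object) {
    cat(sprintf("GroundTruth: %d cells (%s), %d genes (%d up_c1, %d up_c2)\n",
        length(object@cellClass),
        paste(sprintf("%s=%d", names(table(object@cellClass)),
                      as.integer(table(object@cellClass))), collapse = ", "),
        length(object@geneDEFlag),
        sum(object@geneDEFlag == "up_c1"),
        sum(object@geneDEFlag == "up_c2")))
})

#' Consensus clustering result
#'
#' @slot consensus list of cell-by-cell co-assignment matrices, one per k.
#' @slot labels integer cluster labels at the selected k.
#' @slot silhouette named numeric, average silhouette width per k.
#' @slot kSelected integer, silhouette-selected cluster count.
#' @slot method character tag.
#'
#' @exportClass ConsensusResult
setClass("ConsensusResult",
    representation(
        consensus = "list",
        labels = "integer",
        silhouette = "numeric",
        kSelected = "integer",
        method = "character"
    )
)

setMethod("show", "ConsensusResult", function(object) {
    cat(sprintf("ConsensusResult (%s): k = %s selected from {%s}\n",
        object@method, object@kSelected,
        paste(names(object@silhouette), collapse = ",")))
    cat("  avg silhouette width:",
        paste(sprintf("%s:%.3f", names(object@silhouette),
                      object@silhouette), collapse = " "), "\n")
    cat("  cluster sizes:",
        paste(as.integer(table(object@labels)), collapse = "/"), "\n")
})

#' @describeIn ConsensusResult labels at the selected k.
#' @param x a \code{ConsensusResult}.
#' @export
clusterLabels <- function(x) x@labels

#' @describeIn ConsensusResult per-k average silhouette widths.
#' @export
silhouetteByK <- function(x) x@silhouette

#' @describeIn ConsensusResult consensus matrix for cluster count \code{k}.
#' @param k cluster count.
#' @export
consensusMatrix <- function(x, k) x@consensus[[as.character(k)]]
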