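#' @importFrom minpack.lm nlsLM
#' @importFrom stats coef nls sd
NULL

# centered running mean via cumsum; k <= 1 returns x unchanged
.runmean <- function(x, k) {
    if (k <= 1L) return(x)
    n <- length(x)
    cs <- cumsum(c(0, x))
    half <- k %/% 2L
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

.stimWindow <- function(trace) {
    sp <- stimParams(trace)
    fs <- samplingRate(trace)
    list(onset = sp$onset, offset = sp$offset,
         iOn = as.integer(round(sp$onset * fs)) + 1L,
         iOff = as.integer(round(sp$offset * fs)))
}

#' Resting membrane potential
#'
#' Arithmetic mean of a rest-segment voltage recording (the convention is an
#' average over the full segment, nominally 30 s at 5 kHz).
#'
#' @param trace a \code{"rest"} voltage \linkS4class{Trace} of at least 1 s.
#' @return V_rest in mV.
#' @examples
#' measureVrest(Trace(rep(-64, 5000), 5000, "mV", "rest"))
#' @export
measureVrest <- function(trace) {
    if (traceUnits(trace) != "mV")
        stop("measureVrest requires a voltage trace")
    if (length(traceSignal(trace)) / samplingRate(trace) < 1)
        stop("rest segment must be at least 1 s")
    mean(traceSignal(trace))
}

#' Membrane time constant from a hyperpolarizing step
#'
#' Fits the initial phase of the response to a negative current step (by
#' convention -200 pA, 200 ms) with a mono-exponential
#' \eqn{V(t) = V_\infty + (V_0 - V_\infty) e^{-t/\tau}} by least squares.
#' The fit window runs from stimulus onset to \code{windowFactor} times a
#' coarse 63\% estimate so that slow sag components do not bias the fast
#' charging phase.
#'
#' @param trace a \code{"step"} \linkS4class{Trace} with known onset.
#' @param windowFactor fit window length in units of the coarse tau.
#' @return tau_m in ms, or \code{NA} if the response is degenerate or the
#'   fit fails.
#' @export
fitMembraneTau <- function(trace, windowFactor = 5) {
    w <- .stimWindow(trace)
    fs <- samplingRate(trace)
    v <- traceSignal(trace)
    v0 <- mean(v[seq_len(w$iOn - 1L)])
    stepIdx <- w$iOn:w$iOff
    q <- stepIdx[seq.int(floor(length(stepIdx) * 0.75) + 1L,
                         length(stepIdx))]
    vss <- mean(v[q])
    if (abs(vss - v0) < 1) return(NA_real_)   # flat response: flagged missing
    target <- v0 + 0.632 * (vss - v0)
    vs <- .runmean(v, max(1L, round(2e-5 * fs)))
    crossed <- if (vss < v0) vs[stepIdx] <= target else vs[stepIdx] >= target
    if (!any(crossed)) return(NA_real_)
    coarse <- (which(crossed)[1] - 1L) / fs * 1000          # ms
    coarse <- max(coarse, 2000 / fs)
    iEnd <- min(w$iOff, w$iOn + ceiling(windowFactor * coarse / 1000 * fs))
    idx <- w$iOn:iEnd
    tt <- (idx - w$iOn) / fs * 1000
    dat <- data.frame(tt = tt, vv = v[idx])
    fit <- tryCatch(
        nlsLM(vv ~ vinf + (vz - vinf) * exp(-tt / tau), data = dat,
              start = list(vinf = vss, vz = v0, tau = coarse),
              lower = c(-Inf, -Inf, 1e-4),
              control = minpack.lm::nls.lm.control(maxiter = 100)),
        error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    unname(coef(fit)["tau"])
}

#' Input and series resistance from a voltage-clamp step
#'
#' From the current response to a small negative command step (by convention
#' -5 mV from a -70 mV holding potential, 200 ms, sampled at 20 kHz):
#' \eqn{R_s = \Delta V / I_{peak}} using the peak of the initial capacitive
#' transient, and \eqn{R_{in} = \Delta V / I_{ss} - R_s} with the steady
#' state taken as the mean over the last quartile of the step.
#'
#' @param trace a \code{"vc_step"} current \linkS4class{Trace}.
#' @return list with \code{rIn} and \code{rS} in MOhm and a logical
#'   \code{flag} raised when the response is suspicious (steady-state
#'   current of the wrong sign, or vanishing transient).
#' @export
measureRinRs <- function(trace) {
    if (traceUnits(trace) != "pA")
        stop("measureRinRs requires a current trace")
    w <- .stimWindow(trace)
    fs <- samplingRate(trace)
    i <- traceSignal(trace)
    dv <- stimParams(trace)$ampMV
    base <- mean(i[seq_len(w$iOn - 1L)])
    stepIdx <- w$iOn:w$iOff
    early <- stepIdx[seq_len(max(2L, round(0.002 * fs)))]
    dev <- i[early] - base
    iPk <- dev[which.max(abs(dev))]
    q <- stepIdx[seq.int(floor(length(stepIdx) * 0.75) + 1L,
                         length(stepIdx))]
    iSS <- mean(i[q]) - base
    if (sign(iSS) != sign(dv) || iSS == 0)
        return(list(rIn = NA_real_, rS = NA_real_, flag = TRUE))
    rS <- dv / iPk * 1000
    rIn <- dv / iSS * 1000 - rS
    flag <- rIn < 1 || rS < 0
    list(rIn = rIn, rS = rS, flag = flag)
}

#' Membrane capacitance from tau and input resistance
#'
#' \eqn{C_m = \tau_m / R_{in}} (ms over MOhm gives nF; reported in pF).
#' This is the passive-membrane convention; values are comparable to, but
#' not identical with, amplifier capacitance-compensation readouts.
#'
#' @param tauM membrane time constant, ms.
#' @param rIn input resistance, MOhm.
#' @return C_m in pF; missing inputs propagate.
#' @examples
#' deriveCm(1.056, 96)   # ~11 pF
#' @export
deriveCm <- function(tauM, rIn) {
    ifelse(is.na(tauM) | is.na(rIn) | tauM <= 0 | rIn <= 0,
           NA_real_, tauM / rIn * 1000)
}

#' Detect action potentials in a voltage trace
#'
#' Peaks above an absolute voltage criterion separated by at least a
#' refractory interval.  For each peak the spike threshold is the voltage at
#' the most recent point before the peak where the (lightly smoothed) rate
#' of rise dV/dt is below \code{dvdtCrit}; amplitude is referenced to the
#' pre-stimulus baseline and halfwidth is measured at 50\% of the peak
#' amplitude from baseline.
#'
#' @param trace a voltage \linkS4class{Trace}.
#' @param peakThreshold absolute peak criterion, mV (default -10).
#' @param dvdtCrit threshold criterion on dV/dt, V/s (default 10).
#' @param refractoryMs minimum peak separation, ms.
#' @param window optional c(start, end) in seconds restricting detection.
#' @return data.frame with one row per AP: \code{peak_time} (ms),
#'   \code{peak_v}, \code{threshold_v}, \code{amplitude}, \code{halfwidth},
#'   \code{latency} (ms from stimulus onset, NA without a stimulus).
#' @export
detectAPs <- function(trace, peakThreshold = -10, dvdtCrit = 10,
                      refractoryMs = 1, window = NULL) {
    if (traceUnits(trace) != "mV")
        stop("detectAPs requires a voltage trace")
    v <- traceSignal(trace)
    fs <- samplingRate(trace)
    sp <- stimParams(trace)
    onset <- sp$onset
    empty <- data.frame(peak_time = numeric(0), peak_v = numeric(0),
                        threshold_v = numeric(0), amplitude = numeric(0),
                        halfwidth = numeric(0), latency = numeric(0))
    baseline <- if (!is.null(onset))
        mean(v[seq_len(max(1L, round(onset * fs)))])
    else mean(v[seq_len(max(1L, length(v) %/% 10))])

    lo <- 1L; hi <- length(v)
    if (!is.null(window)) {
        lo <- max(1L, as.integer(round(window[1] * fs)) + 1L)
        hi <- min(length(v), as.integer(round(window[2] * fs)))
    }
    above <- which(v > peakThreshold)
    above <- above[above >= lo & above <= hi]
    if (!length(above)) return(empty)
    runs <- split(above, cumsum(c(1L, diff(above) > 1L)))
    peaks <- vapply(runs, function(r) r[which.max(v[r])], integer(1))
    peaks <- sort(unname(peaks))
    refN <- round(refractoryMs / 1000 * fs)
    keep <- logical(length(peaks))
    last <- -Inf
    for (j in seq_along(peaks)) {
        if (peaks[j] - last >= refN) { keep[j] <- TRUE; last <- peaks[j] }
    }
    peaks <- peaks[keep]

    vs <- .runmean(v, max(1L, round(1e-4 * fs)))
    dvdt <- c(0, diff(vs)) * fs / 1000                     # mV/ms = V/s
    half <- baseline + 0.5 * (v[peaks] - baseline)
    res <- lapply(seq_along(peaks), function(j) {
        pk <- peaks[j]
        jb <- pk
        limit <- max(1L, pk - round(0.005 * fs))
        while (jb > limit && dvdt[jb] > dvdtCrit) jb <- jb - 1L
        thrV <- vs[jb]
        hl <- half[j]
        il <- pk
        while (il > 1L && v[il] > hl) il <- il - 1L
        tl <- if (il < pk && v[il + 1L] != v[il])
            il + (hl - v[il]) / (v[il + 1L] - v[il]) else il
        ir <- pk
        while (ir < length(v) && v[ir] > hl) ir <- ir + 1L
        tr <- if (ir > pk && v[ir - 1L] != v[ir])
            (ir - 1L) + (hl - v[ir - 1L]) / (v[ir] - v[ir - 1L]) else ir
        data.frame(
            peak_time = (pk - 1L) / fs * 1000,
            peak_v = v[pk],
            threshold_v = thrV,
            amplitude = v[pk] - baseline,
            halfwidth = (tr - tl) / fs * 1000,
            latency = if (!is.null(onset))
                (pk - 1L) / fs * 1000 - onset * 1000 else NA_real_)
    })
    do.call(rbind, res)
}

.countStepAPs <- function(trace, ...) {
    sp <- stimParams(trace)
    nrow(detectAPs(trace, window = c(sp$onset, sp$offset), ...))
}

#' Approximate rheobase from a current-step family
#'
#' The smallest step amplitude whose response contains at least one action
#' potential; the family runs -200..1000 pA in 50-pA increments by default,
#' so rheobase is resolved to one increment.
#'
#' @param stepTraces list of \code{"step"} \linkS4class{Trace}s ordered by
#'   increasing amplitude (see \code{\link{stepFamily}}).
#' @param ... passed to \code{\link{detectAPs}}.
#' @return rheobase in pA, or \code{NA} if no step elicits an AP.
#' @export
approximateRheobase <- function(stepTraces, ...) {
    amps <- vapply(stepTraces, function(t) stimParams(t)$amp, numeric(1))
    if (is.unsorted(amps, strictly = TRUE))
        stop("step family must be ordered by strictly increasing amplitude")
    for (j in which(amps > 0)) {
        if (.countStepAPs(stepTraces[[j]], ...) >= 1L)
            return(amps[j])
    }
    NA_real_
}

#' Classify the firing pattern of a neuron
#'
#' First-AP latency is measured at rheobase; the AP count is measured
#' 150 pA above rheobase.  Classification rule (thresholds configurable):
#' \emph{Delayed} if the first-AP latency is at least
#' \code{latencyThreshold} (default 15 ms; Delayed latencies run 25--180 ms
#' versus ~2.9 / ~7.0 ms for Onset / Sustained); otherwise \emph{Onset} if
#' the AP count at rheobase + 150 pA is at most \code{onsetMaxAPs} (default
#' 5), else \emph{Sustained}.
#'
#' @param stepTraces ordered step family.
#' @param rheobase pA; computed from the family when \code{NULL}.
#' @param latencyThreshold ms.
#' @param onsetMaxAPs maximal AP count for the Onset class.
#' @param deltaI current above rheobase used for the count, pA.
#' @param ... passed to \code{\link{detectAPs}}.
#' @return list with \code{firingClass} (factor level as character, or NA),
#'   \code{firstAPLatency} (ms) and \code{apCountHigh}.
#' @export
classifyFiringPattern <- function(stepTraces, rheobase = NULL,
                                  latencyThreshold = 15, onsetMaxAPs = 5,
                                  deltaI = 150, ...) {
    if (is.null(rheobase)) rheobase <- approximateRheobase(stepTraces, ...)
    if (is.na(rheobase))
        return(list(firingClass = NA_character_,
                    firstAPLatency = NA_real_, apCountHigh = NA_integer_))
    amps <- vapply(stepTraces, function(t) stimParams(t)$amp, numeric(1))
    atRheo <- stepTraces[[which.min(abs(amps - rheobase))]]
    sp <- stimParams(atRheo)
    aps <- detectAPs(atRheo, window = c(sp$onset, sp$offset), ...)
    lat <- if (nrow(aps)) aps$latency[1] else NA_real_
    iHigh <- which.min(abs(amps - (rheobase + deltaI)))
    nHigh <- .countStepAPs(stepTraces[[iHigh]], ...)
    cls <- if (is.na(lat)) NA_character_
        else if (lat >= latencyThreshold) "Delayed"
        else if (nHigh <= onsetMaxAPs) "Onset"
        else "Sustained"
    list(firingClass = cls, firstAPLatency = lat,
         apCountHigh = as.integer(nHigh))
}

#' Voltage sag and rebound from a hyperpolarizing step
#'
#' Sag amplitude is \eqn{|V_{peak} - V_{ss}|}: the peak hyperpolarization
#' (searched in the first \code{peakWindowMs} of the step, on a lightly
#' smoothed trace) relative to the steady state (mean over the last quartile
#' of the step).  Rebound is flagged when the post-offset voltage exceeds
#' the pre-stimulus baseline by at least twice the noise SD for at least
#' \code{reboundMinMs}.
#'
#' @param trace the -200 pA step response.
#' @param peakWindowMs search window for the sag peak, ms.
#' @param smoothMs smoothing window, ms.
#' @param reboundMinMs minimum supra-baseline duration, ms.
#' @return list with \code{sag} (mV) and \code{rebound} (logical).
#' @export
measureSag <- function(trace, peakWindowMs = 50, smoothMs = 1,
                       reboundMinMs = 5) {
    w <- .stimWindow(trace)
    fs <- samplingRate(trace)
    v <- traceSignal(trace)
    vs <- .runmean(v, max(1L, round(smoothMs / 1000 * fs)))
    v0 <- mean(v[seq_len(w$iOn - 1L)])
    stepIdx <- w$iOn:w$iOff
    q <- stepIdx[seq.int(floor(length(stepIdx) * 0.75) + 1L,
                         length(stepIdx))]
    vss <- mean(v[q])
    peakIdx <- stepIdx[seq_len(min(length(stepIdx),
                                   round(peakWindowMs / 1000 * fs)))]
    sag <- max(0, vss - min(vs[peakIdx]))
    noiseSD <- sd(vs[seq_len(w$iOn - 1L)])
    thr <- v0 + 2 * max(noiseSD, 0.05)
    post <- vs[seq.int(min(w$iOff + 1L, length(vs)), length(vs))]
    runs <- rle(post > thr)
    minN <- round(reboundMinMs / 1000 * fs)
    rebound <- any(runs$lengths[runs$values] >= minN)
    list(sag = sag, rebound = rebound)
}

# kinetics of one averaged PSC waveform; dir = +1 outward / -1 inward
.pscKinetics <- function(avg, fs, preN, dir) {
    base <- mean(avg[seq_len(max(1L, preN - round(0.001 * fs)))])
    dev <- (avg - base) * dir
    searchIdx <- preN:length(avg)
    pk <- searchIdx[which.max(dev[searchIdx])]
    amp <- dev[pk]
    lvl <- function(f) base + dir * f * amp
    crossT <- function(iFrom, iTo, level) {
        idx <- iFrom:iTo
        cr <- which(dev[idx] >= (level - base) * dir)
        if (!length(cr)) return(NA_real_)
        j <- idx[cr[1]]
        if (j > 1 && dev[j] != dev[j - 1]) {
            frac <- ((level - base) * dir - dev[j - 1]) /
                    (dev[j] - dev[j - 1])
            (j - 1 + frac - 1) / fs * 1000
        } else (j - 1) / fs * 1000
    }
    t10 <- crossT(preN, pk, lvl(0.1))
    t90 <- crossT(preN, pk, lvl(0.9))
    tail <- dev[pk:length(avg)]
    below <- which(tail <= 0.37 * amp)
    decay <- if (length(below)) {
        j <- below[1]
        frac <- if (j > 1 && tail[j] != tail[j - 1])
            (tail[j - 1] - 0.37 * amp) / (tail[j - 1] - tail[j]) else 0
        (j - 2 + frac) / fs * 1000
    } else NA_real_
    list(amplitude = amp, rise = t90 - t10, decay = decay)
}

#' Detect spontaneous postsynaptic currents
#'
#' Threshold-crossing detection per polarity on a long current recording at
#' the holding potential: excitatory events (sEPSCs) are inward (negative),
#' inhibitory events (sIPSCs) outward (positive).  The detection threshold
#' is \code{thresholdFactor} times the robust noise SD (MAD).  The first
#' \code{maxEvents} events per polarity (all, if fewer) are aligned on onset
#' and averaged; amplitude, 10--90\% rise time and the 100--37\% decay time
#' are measured on the averaged waveform.
#'
#' @param trace a \code{"psc"} current \linkS4class{Trace}.
#' @param thresholdFactor detection criterion in robust noise SDs.
#' @param maxEvents events entering the average per polarity (default 100).
#' @param refractoryMs minimum onset separation, ms.
#' @return list with elements \code{epsc} and \code{ipsc}, each a list of
#'   \code{times} (s), \code{n}, \code{amplitude} (pA), \code{rise} (ms),
#'   \code{decay} (ms) and \code{lowConfidence} (TRUE below 10 events).
#' @export
detectPSCs <- function(trace, thresholdFactor = 4, maxEvents = 100,
                       refractoryMs = 5) {
    if (traceUnits(trace) != "pA")
        stop("detectPSCs requires a current trace")
    i <- traceSignal(trace)
    fs <- samplingRate(trace)
    med <- median(i)
    sigma <- mad(i)
    if (sigma == 0) sigma <- max(sd(i), .Machine$double.eps)
    preN <- round(0.005 * fs)
    postN <- round(0.05 * fs)
    refN <- round(refractoryMs / 1000 * fs)
    out <- list()
    smoothN <- max(1L, round(2e-4 * fs))        # 0.2 ms anti-noise filter
    minRun <- max(1L, round(1e-4 * fs))         # sustained crossing required
    for (pol in c("epsc", "ipsc")) {
        dir <- if (pol == "epsc") -1 else 1
        dev <- (.runmean(i, smoothN) - med) * dir
        above <- dev > thresholdFactor * sigma
        r <- rle(above)
        ends <- cumsum(r$lengths)
        ok <- r$values & r$lengths >= minRun
        hits <- unlist(lapply(which(ok), function(j)
            seq.int(ends[j] - r$lengths[j] + 1L, ends[j])), use.names = FALSE)
        if (!length(hits)) {
            out[[pol]] <- list(times = numeric(0), n = 0L,
                               amplitude = NA_real_, rise = NA_real_,
                               decay = NA_real_, lowConfidence = TRUE)
            next
        }
        onsets <- hits[c(TRUE, diff(hits) > refN)]
        times <- (onsets - 1L) / fs
        use <- onsets[seq_len(min(maxEvents, length(onsets)))]
        use <- use[use > preN & use + postN <= length(i)]
        if (!length(use)) {
            out[[pol]] <- list(times = times, n = length(onsets),
                               amplitude = NA_real_, rise = NA_real_,
                               decay = NA_real_, lowConfidence = TRUE)
            next
        }
        win <- vapply(use, function(o) i[(o - preN):(o + postN)],
                      numeric(preN + postN + 1L))
        avg <- rowMeans(win)
        kin <- .pscKinetics(avg, fs, preN, dir)
        out[[pol]] <- list(times = times, n = length(onsets),
                           amplitude = kin$amplitude, rise = kin$rise,
                           decay = kin$decay,
                           lowConfidence = length(onsets) < 10L,
                           waveform = avg)
    }
    out
}

#' Names of the default 16-feature electrophysiological vector
#'
#' The downstream PCA / statistics use 16 of the 18 extracted fields:
#' passive properties, rheobase, first-AP latency, sag, AP waveform metrics
#' and six PSC metrics.  Series resistance and the rebound flag are
#' recorded but excluded by default.
#'
#' @return character vector of 16 column names.
#' @export
ephysFeatureNames <- function() {
    c("v_rest", "r_in", "tau_m", "c_m", "rheobase", "first_ap_latency",
      "sag_amp", "ap_amplitude", "ap_halfwidth", "ap_threshold",
      "sepsc_amp", "sepsc_rise", "sepsc_decay",
      "sipsc_amp", "sipsc_rise", "sipsc_decay")
}

#' Extract the per-cell electrophysiological feature vector
#'
#' Assembles the full feature record for one cell from its protocol traces:
#' V_rest from the rest segment, R_in and R_s from the voltage-clamp step,
#' tau_m from the -200 pA response (C_m derived as tau_m / R_in), rheobase
#' and firing classification from the step family, sag and rebound from the
#' -200 pA response, AP waveform metrics from the first AP at rheobase, and
#' sPSC amplitude and kinetics from the 60-s recording.  Missing protocols
#' yield \code{NA} fields, never silent zeros.
#'
#' @param ct a \linkS4class{CellTraces}.
#' @param latencyThreshold,onsetMaxAPs firing-class thresholds, see
#'   \code{\link{classifyFiringPattern}}.
#' @param peakThreshold,dvdtCrit AP detector criteria, see
#'   \code{\link{detectAPs}}.
#' @return one-row data.frame with the 18 feature fields plus
#'   \code{firing_class}.
#' @export
extractFeatureVector <- function(ct, latencyThreshold = 15,
                                 onsetMaxAPs = 5, peakThreshold = -10,
                                 dvdtCrit = 10) {
    out <- as.data.frame(setNames(
        as.list(rep(NA_real_, 18L)),
        c(ephysFeatureNames(), "r_s", "rebound")))
    out$rebound <- NA
    out$firing_class <- NA_character_
    nm <- names(ct)
    if ("rest" %in% nm)
        out$v_rest <- measureVrest(ct[["rest"]])
    if ("vc_step" %in% nm) {
        rr <- measureRinRs(ct[["vc_step"]])
        out$r_in <- rr$rIn; out$r_s <- rr$rS
    }
    steps <- stepFamily(ct)
    if (length(steps)) {
        amps <- vapply(steps, function(t) stimParams(t)$amp, numeric(1))
        neg <- which.min(abs(amps - (-200)))
        if (amps[neg] < 0) {
            out$tau_m <- fitMembraneTau(steps[[neg]])
            sg <- measureSag(steps[[neg]])
            out$sag_amp <- sg$sag; out$rebound <- sg$rebound
        }
        out$c_m <- deriveCm(out$tau_m, out$r_in)
        rheo <- approximateRheobase(steps, peakThreshold = peakThreshold,
                                    dvdtCrit = dvdtCrit)
        out$rheobase <- rheo
        cls <- classifyFiringPattern(steps, rheobase = rheo,
                                     latencyThreshold = latencyThreshold,
                                     onsetMaxAPs = onsetMaxAPs,
                                     peakThreshold = peakThreshold,
                                     dvdtCrit = dvdtCrit)
        out$firing_class <- cls$firingClass
        out$first_ap_latency <- cls$firstAPLatency
        if (!is.na(rheo)) {
            atRheo <- steps[[which.min(abs(amps - rheo))]]
            sp <- stimParams(atRheo)
            aps <- detectAPs(atRheo, window = c(sp$onset, sp$offset),
                             peakThreshold = peakThreshold,
                             dvdtCrit = dvdtCrit)
            if (nrow(aps)) {
                out$ap_amplitude <- aps$amplitude[1]
                out$ap_halfwidth <- aps$halfwidth[1]
                out$ap_threshold <- aps$threshold_v[1]
            }
        }
    }
    if ("psc" %in% nm) {
        ps <- detectPSCs(ct[["psc"]])
        out$sepsc_amp <- ps$epsc$amplitude
        out$sepsc_rise <- ps$epsc$rise
        out$sepsc_decay <- ps$epsc$decay
        out$sipsc_amp <- ps$ipsc$amplitude
        out$sipsc_rise <- ps$ipsc$rise
        out$sipsc_decay <- ps$ipsc$decay
    }
    out
}

#' Extract features for every cell of a TraceSet
#'
#' @param ts a \linkS4class{TraceSet}.
#' @param ... passed to \code{\link{extractFeatureVector}}.
#' @return data.frame with one row per cell, rownames and a \code{cell}
#'   column carrying the cell ids.
#' @export
extractFeatures <- function(ts, ...) {
    rows <- lapply(ts, extractFeatureVector, ...)
    df <- do.call(rbind, rows)
    df$cell <- names(ts)
    rownames(df) <- names(ts)
    df
}

#' Simulate traces and extract features cell by cell
#'
#' Streaming convenience used by the pipeline and by recovery tests:
#' generates each neuron's traces, extracts its feature vector, and discards
#' the traces, keeping memory flat for large cohorts.
#'
#' @inheritParams simulateTraces
#' @param ... passed to \code{\link{extractFeatureVector}}.
#' @return data.frame as for \code{\link{extractFeatures}}.
#' @export
simulateFeatures <- function(config, truth, cells = NULL,
                             protocols = c("rest", "step", "vc_step",
                                           "psc"),
                             noise = TRUE, seed = config@seed, ...) {
    te <- trueEphys(truth)
    neuron <- te$cell[truth@cellClass != "NegControl"]
    if (is.null(cells)) cells <- neuron
    rows <- vector("list", length(cells))
    for (j in seq_along(cells)) {
        ts1 <- simulateTraces(config, truth, cells = cells[j],
                              protocols = protocols, noise = noise,
                              seed = seed)
        rows[[j]] <- extractFeatureVector(ts1[[1]], ...)
    }
    df <- do.call(rbind, rows)
    df$cell <- cells
    rownames(df) <- cells
    df
}
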