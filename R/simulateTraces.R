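#' @importFrom stats approx
NULL

# Peak times (ms from stimulus onset) dictated by the class firing rule.
.apTimes <- function(firing, amp, rheo, latency, stepMs) {
    if (amp < rheo) return(numeric(0))
    lastOk <- stepMs - 2
    if (latency > lastOk) return(numeric(0))
    switch(firing$rule,
        onset = {
            n <- min(1L + floor((amp - rheo) / firing$extraPer),
                     firing$maxAPs)
            t <- latency + firing$burstInterval * (seq_len(n) - 1L)
            t[t <= lastOk]
        },
        sustained = ,
        delayed = {
            rate <- firing$rate0 + firing$gain * (amp - rheo)
            iv <- 1000 / rate
            latency + iv * (0:floor((lastOk - latency) / iv))
        },
        stop("unknown firing rule: ", firing$rule))
}

# Overwrite the trace with linear-flank spike templates whose PEAK sits at
# the requested sample.  Flanks run from the local (subthreshold) trace value
# up to apPeak, so templates remain continuous with the carrier.
.insertAPs <- function(v, fs, onsetIdx, peakTimesMs, ap) {
    if (!length(peakTimesMs)) return(v)
    riseN <- max(2L, round(ap$rise * fs / 1000))
    fallN <- max(2L, round(ap$fall * fs / 1000))
    n <- length(v)
    for (tm in peakTimesMs) {
        pk <- onsetIdx + as.integer(round(tm * fs / 1000))
        i0 <- max(1L, pk - riseN); i1 <- min(n, pk + fallN)
        if (pk < 1L || pk > n) next
        footUp <- v[i0]; footDn <- v[i1]
        up <- seq(footUp, ap$peak, length.out = pk - i0 + 1L)
        dn <- seq(ap$peak, footDn, length.out = i1 - pk + 1L)
        v[i0:pk] <- pmax(v[i0:pk], up)
        v[pk:i1] <- pmax(v[pk:i1], dn)
    }
    v
}

# One current-clamp step sweep: 50 ms baseline, `stepDur` step, 150 ms tail.
.makeStepTrace <- function(p, classPar, amp, config, noise = TRUE) {
    fs <- config@samplingRates$step
    dt <- 1 / fs
    pre <- 0.05; stepDur <- config@stepDuration; post <- 0.15
    nPre <- round(pre * fs); nStep <- round(stepDur * fs)
    nPost <- round(post * fs)
    tauS <- p$tauM / 1000
    dV <- amp * p$rIn / 1000                    # pA * MOhm / 1000 -> mV

    ts <- (seq_len(nStep) - 1L) * dt
    vStep <- p$vRest + dV * (1 - exp(-ts / tauS))
    vStep <- pmin(vStep, classPar$ap$clip)      # depolarization saturates
    if (amp < 0 && p$sagComponent > 0) {
        tauSagS <- classPar$tauSag / 1000
        w <- (1 - exp(-ts / tauS)) * exp(-ts / tauSagS)
        vStep <- vStep - p$sagComponent * (abs(amp) / 200) * w / max(w)
    }
    tp <- (seq_len(nPost) - 1L) * dt
    vEnd <- vStep[nStep]
    vPost <- p$vRest + (vEnd - p$vRest) * exp(-tp / tauS)
    if (amp < 0 && p$reboundAmp > 0) {
        tauRebS <- classPar$rebound$tau / 1000
        w <- (1 - exp(-tp / tauS)) * exp(-tp / tauRebS)
        vPost <- vPost + p$reboundAmp * (abs(amp) / 200) * w / max(w)
    }
    v <- c(rep(p$vRest, nPre), vStep, vPost)
    pk <- .apTimes(classPar$firing, amp, p$rheobase, p$latency,
                   stepDur * 1000)
    v <- .insertAPs(v, fs, nPre + 1L, pk, classPar$ap)
    if (noise && config@noiseSD$voltage > 0)
        v <- v + rnorm(length(v), 0, config@noiseSD$voltage)
    Trace(v, fs, "mV", "step",
          list(amp = amp, onset = pre, offset = pre + stepDur))
}

# Voltage-clamp -5 mV step from -70 mV; holding current is offset to zero.
.makeVCTrace <- function(p, config, noise = TRUE) {
    fs <- config@samplingRates$vc
    dt <- 1 / fs
    pre <- 0.05; stepDur <- 0.2; post <- 0.05
    nPre <- round(pre * fs); nStep <- round(stepDur * fs)
    nPost <- round(post * fs)
    dVmV <- -5
    iPk <- dVmV / p$rS * 1000                  # mV / MOhm -> nA -> pA
    iSS <- dVmV / (p$rS + p$rIn) * 1000
    tauC <- p$rS * p$cM * (p$rIn / (p$rS + p$rIn)) * 1e-6   # seconds
    ts <- (seq_len(nStep) - 1L) * dt
    iStep <- iSS + (iPk - iSS) * exp(-ts / tauC)
    tp <- (seq_len(nPost) - 1L) * dt
    iPost <- -(iPk - iSS) * exp(-tp / tauC)
    i <- c(rep(0, nPre), iStep, iPost)
    if (noise && config@noiseSD$current > 0)
        i <- i + rnorm(length(i), 0, config@noiseSD$current)
    Trace(i, fs, "pA", "vc_step",
          list(ampMV = dVmV, vHold = -70, onset = pre,
               offset = pre + stepDur))
}

.makeRestTrace <- function(p, config, noise = TRUE) {
    fs <- config@samplingRates$rest
    n <- round(config@restDuration * fs)
    v <- rep(p$vRest, n)
    if (noise && config@noiseSD$voltage > 0)
        v <- v + rnorm(n, 0, config@noiseSD$voltage)
    Trace(v, fs, "mV", "rest", list())
}

# biexponential kernel normalized to unit peak
.pscKernel <- function(fs, riseMs, decayMs) {
    tauR <- riseMs / 1000; tauD <- decayMs / 1000
    tEnd <- 8 * tauD
    t <- seq(0, tEnd, by = 1 / fs)
    k <- exp(-t / tauD) - exp(-t / tauR)
    k / max(k)
}

#' Simulate a spontaneous PSC recording for one cell
#'
#' Poisson-timed biexponential events on Gaussian current noise; excitatory
#' events (sEPSCs) are inward (negative), inhibitory events (sIPSCs) outward
#' (positive).  Planted onset times and amplitudes are recorded in the
#' returned trace's \code{stimParams} so detector recall is measurable.
#'
#' @param p one-row data.frame of cell parameters (from
#'   \code{\link{trueEphys}}).
#' @param classPar per-class parameter list entry.
#' @param config a \linkS4class{SimConfig}.
#' @param noise include additive current noise.
#' @return A \code{"psc"} \linkS4class{Trace} (60 s by default).
#' @keywords internal
.makePSCTrace <- function(p, classPar, config, noise = TRUE) {
    fs <- config@samplingRates$psc
    dur <- config@pscDuration
    n <- round(dur * fs)
    i <- if (noise && config@noiseSD$current > 0)
        rnorm(n, 0, config@noiseSD$current) else numeric(n)
    stim <- list(vHold = -70)
    for (pol in c("epsc", "ipsc")) {
        pp <- classPar$psc[[pol]]
        sign <- if (pol == "epsc") -1 else 1
        nEv <- rpois(1, pp$rate * dur)
        times <- sort(runif(nEv, 0.05, dur - 0.1))
        amps <- rlnorm(nEv, log(pp$amp), pp$ampCV)
        kern <- .pscKernel(fs, pp$rise, pp$decay)
        kl <- length(kern)
        for (e in seq_len(nEv)) {
            i0 <- as.integer(round(times[e] * fs)) + 1L
            i1 <- min(n, i0 + kl - 1L)
            i[i0:i1] <- i[i0:i1] + sign * amps[e] * kern[seq_len(i1 - i0 + 1L)]
        }
        stim[[paste0(pol, "Times")]] <- times
        stim[[paste0(pol, "Amps")]] <- amps
    }
    Trace(i, fs, "pA", "psc", stim)
}

# triangular current pulses (rise 1.5 ms, decay 3.5 ms), RC-integrated
.makeTriangleTraces <- function(p, classPar, config, noise = TRUE,
                                repeats = 10L) {
    fs <- config@samplingRates$triangle
    dt <- 1 / fs
    pre <- 0.02; riseMs <- 1.5; fallMs <- 3.5; post <- 0.03
    peakI <- p$rheobase + 100
    nPre <- round(pre * fs)
    nRise <- round(riseMs / 1000 * fs); nFall <- round(fallMs / 1000 * fs)
    nPost <- round(post * fs)
    iWave <- c(rep(0, nPre),
               seq(0, peakI, length.out = nRise),
               seq(peakI, 0, length.out = nFall),
               rep(0, nPost))
    tauS <- p$tauM / 1000
    out <- vector("list", repeats)
    for (r in seq_len(repeats)) {
        v <- numeric(length(iWave)); v[1] <- p$vRest
        drive <- p$vRest + iWave * p$rIn / 1000
        a <- dt / tauS
        for (k in seq_len(length(iWave) - 1L))
            v[k + 1L] <- v[k] + a * (drive[k] - v[k])
        v <- pmin(v, classPar$ap$clip)
        if (peakI >= p$rheobase)
            v <- .insertAPs(v, fs, nPre + nRise, 0.5, classPar$ap)
        if (noise && config@noiseSD$voltage > 0)
            v <- v + rnorm(length(v), 0, config@noiseSD$voltage)
        out[[r]] <- Trace(v, fs, "mV", "triangle",
                          list(peakAmp = peakI, onset = pre,
                               riseMs = riseMs, fallMs = fallMs))
    }
    out
}

.makeCellTraces <- function(p, classPar, config, noise, protocols) {
    tr <- list()
    if ("rest" %in% protocols)
        tr$rest <- .makeRestTrace(p, config, noise)
    if ("step" %in% protocols) {
        amps <- seq(config@stepRange[1], config@stepRange[2],
                    by = config@stepIncrement)
        amps <- amps[amps != 0]
        for (a in amps)
            tr[[sprintf("step_%d", as.integer(a))]] <-
                .makeStepTrace(p, classPar, a, config, noise)
    }
    if ("vc_step" %in% protocols)
        tr$vc_step <- .makeVCTrace(p, config, noise)
    if ("psc" %in% protocols)
        tr$psc <- .makePSCTrace(p, classPar, config, noise)
    if ("triangle" %in% protocols) {
        tri <- .makeTriangleTraces(p, classPar, config, noise)
        names(tri) <- sprintf("triangle_%02d", seq_along(tri))
        tr <- c(tr, tri)
    }
    do.call(CellTraces, tr)
}

#' Simulate electrophysiological traces for the cells of a study
#'
#' Builds parametric traces per neuron from the planted parameters in
#' \code{truth}: subthreshold responses follow the closed-form RC charging
#' curve \eqn{V(t) = V_{rest} + I R_{in} (1 - e^{-t/\tau_m})} with
#' \eqn{\tau_m = R_{in} C_m}; hyperpolarizing steps in pLSO classes add a
#' slow opposing sag component and a post-offset rebound; action potentials
#' are inserted as stereotyped templates at times dictated by the class
#' firing rule (onset burst, regular sustained train with rate proportional
#' to suprathreshold current, or delayed train starting 25--180 ms after
#' onset); Gaussian noise is added throughout.  Negative-control cells have
#' no traces.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param truth the matching \linkS4class{GroundTruth}.
#' @param cells cell ids to simulate (default: all neurons).
#' @param protocols subset of
#'   \code{c("rest","step","vc_step","psc","triangle")}.
#' @param noise logical; disable for exact closed-form traces.
#' @param seed integer; each cell uses the substream \code{seed + index} so
#'   the full set is reproducible and per-cell generation order-free.
#' @return A \linkS4class{TraceSet} named by cell id.
#' @examples
#' cfg <- simConfig(nOnset = 1, nSustained = 0, nDelayed = 1,
#'                  nGenes = 100, nMarkersC1 = 10, nMarkersC2 = 5)
#' sim <- simulateCounts(cfg)
#' ts <- simulateTraces(cfg, sim$truth, protocols = c("rest", "step"))
#' ts
#' @export
simulateTraces <- function(config, truth,
                           cells = NULL,
                           protocols = c("rest", "step", "vc_step", "psc",
                                         "triangle"),
                           noise = TRUE, seed = config@seed) {
    te <- trueEphys(truth)
    neuron <- te$cell[truth@cellClass != "NegControl"]
    if (is.null(cells)) cells <- neuron
    if (!all(cells %in% neuron))
        stop("traces exist only for neurons (not negative controls)")
    protocols <- match.arg(protocols, several.ok = TRUE)
    if (config@samplingRates$step < 2000)
        stop("sampling rate below template bandwidth")
    out <- vector("list", length(cells))
    names(out) <- cells
    for (cid in cells) {
        idx <- match(cid, te$cell)
        set.seed(seed + idx)
        p <- te[idx, ]
        classPar <- config@ephysParams[[p$class]]
        out[[cid]] <- .makeCellTraces(p, classPar, config, noise, protocols)
    }
    do.call(TraceSet, out)
}
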