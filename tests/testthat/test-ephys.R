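test_that("resting potential is the segment mean with the expected error", {
    expect_identical(measureVrest(Trace(rep(-64, 5000), 5000, "mV", "rest")),
                     -64)
    set.seed(1)
    n <- 150000                       # 30 s at 5 kHz
    tr <- Trace(rnorm(n, -64, 0.5), 5000, "mV", "rest")
    expect_lt(abs(measureVrest(tr) + 64), 6 * 0.5 / sqrt(n))
    expect_error(measureVrest(Trace(rep(0, 5000), 5000, "pA", "psc")),
                 "voltage")
    expect_error(measureVrest(Trace(rep(-64, 100), 5000, "mV", "rest")),
                 "at least 1 s")
})

test_that("membrane time constant fits recover planted values", {
    nc <- noiselessCells()
    # sag-free response: recovery within 1%
    cid <- nc$ids[["Delayed"]]
    tau <- fitMembraneTau(nc$ts[[cid]][["step_-200"]])
    expect_lt(abs(tau - nc$te[cid, "tauM"]) / nc$te[cid, "tauM"], 0.01)
    # with a slow sag component (tau_sag >= 10x tau_m): within 10%
    cid2 <- nc$ids[["Onset"]]
    tau2 <- fitMembraneTau(nc$ts[[cid2]][["step_-200"]])
    expect_lt(abs(tau2 - nc$te[cid2, "tauM"]) / nc$te[cid2, "tauM"], 0.10)
    # flat trace is a flagged missing value
    flat <- Trace(rep(-64, 20000), 50000, "mV", "step",
                  list(amp = -200, onset = 0.05, offset = 0.25))
    expect_true(is.na(fitMembraneTau(flat)))
})

test_that("input and series resistance follow Ohm's law on the VC step", {
    fs <- 20000
    mk <- function(iStep) {
        Trace(c(rep(0, fs * 0.05), iStep), fs, "pA", "vc_step",
              list(ampMV = -5, vHold = -70, onset = 0.05, offset = 0.25))
    }
    # negligible transient: R_in ~ dV / I_ss
    n <- fs * 0.2
    r <- measureRinRs(mk(rep(-50, n)))
    expect_false(is.na(r$rIn))
    expect_lt(abs(r$rIn + r$rS - 100), 0.5)
    # no transient at all means R_s absorbs everything: flagged suspicious
    expect_true(r$flag || r$rS < 5)
    # generator default recovers ~96 MOhm within 1%
    nc <- noiselessCells()
    cid <- nc$ids[["Onset"]]
    rr <- measureRinRs(nc$ts[[cid]][["vc_step"]])
    expect_lt(abs(rr$rIn - nc$te[cid, "rIn"]) / nc$te[cid, "rIn"], 0.01)
    expect_lt(abs(rr$rS - nc$te[cid, "rS"]) / nc$te[cid, "rS"], 0.05)
    # wrong-sign steady state is flagged
    bad <- mk(rep(50, n))
    expect_true(measureRinRs(bad)$flag)
})

test_that("capacitance derivation and missing-value propagation", {
    expect_lt(abs(deriveCm(1.056, 96) - 11.0), 0.1)
    expect_identical(deriveCm(1, 1000), 1)
    expect_true(is.na(deriveCm(NA_real_, 96)))
    expect_true(is.na(deriveCm(1.1, NA_real_)))
})

test_that("AP detection matches inserted templates and closed forms", {
    fs <- 50000
    base <- rep(-64, 0.1 * fs)
    sub <- Trace(base, fs, "mV", "step",
                 list(amp = 100, onset = 0.02, offset = 0.08))
    expect_identical(nrow(detectAPs(sub)), 0L)
    # isoceles-triangle spike of base b: halfwidth measured at 50% of the
    # peak amplitude from baseline equals b/2
    v <- base
    pk <- 0.05 * fs
    riseN <- 0.0004 * fs; fallN <- 0.0004 * fs        # b = 0.8 ms
    v[(pk - riseN):pk] <- seq(-64, 20, length.out = riseN + 1)
    v[pk:(pk + fallN)] <- seq(20, -64, length.out = fallN + 1)
    tr <- Trace(v, fs, "mV", "step",
                list(amp = 300, onset = 0.02, offset = 0.08))
    aps <- detectAPs(tr)
    expect_identical(nrow(aps), 1L)
    expect_lt(abs(aps$halfwidth - 0.4), 0.05)
    expect_lt(abs(aps$amplitude - 84), 0.5)
    expect_lt(abs(aps$peak_time - 50), 0.05)
    expect_lt(aps$threshold_v, -50)   # foot of the spike, near baseline
})

test_that("rheobase is resolved to one 50-pA increment", {
    nc <- noiselessCells()
    for (cl in c("Onset", "Sustained", "Delayed")) {
        cid <- nc$ids[[cl]]
        st <- stepFamily(nc$ts[[cid]])
        rheo <- approximateRheobase(st)
        tru <- nc$te[cid, "rheobase"]
        expect_gte(rheo, tru)
        expect_lt(rheo - tru, 50 + 1e-9)
    }
    # no APs anywhere: missing
    cid <- nc$ids[["Onset"]]
    st <- stepFamily(nc$ts[[cid]])
    amps <- vapply(st, function(t) stimParams(t)$amp, numeric(1))
    subOnly <- st[amps < nc$te[cid, "rheobase"]]
    expect_true(is.na(approximateRheobase(subOnly)))
    expect_error(approximateRheobase(rev(st)), "ordered")
})

test_that("firing-pattern classification separates the three classes", {
    nc <- noiselessCells()
    for (cl in c("Onset", "Sustained", "Delayed")) {
        cid <- nc$ids[[cl]]
        res <- classifyFiringPattern(stepFamily(nc$ts[[cid]]))
        expect_identical(res$firingClass, cl)
        expect_lt(abs(res$firstAPLatency - nc$te[cid, "latency"]), 0.5)
    }
    # delayed latencies live in the 25-180 ms range, pLSO well below 15
    expect_gte(nc$te[nc$ids[["Delayed"]], "latency"], 25)
    expect_lt(nc$te[nc$ids[["Onset"]], "latency"], 15)
    # missing rheobase propagates
    st <- stepFamily(nc$ts[[nc$ids[["Onset"]]]])
    amps <- vapply(st, function(t) stimParams(t)$amp, numeric(1))
    res <- classifyFiringPattern(st[amps < 0])
    expect_true(is.na(res$firingClass))
})

test_that("sag measurement follows its defining arithmetic", {
    fs <- 50000
    pre <- rep(-64, 0.05 * fs)
    stepN <- 0.2 * fs
    # dip to -90 early, settle at -80
    t <- seq_len(stepN) / fs * 1000
    vstep <- -80 - 10 * exp(-pmax(t - 3, 0) / 10) * (t > 1) -
        16 * pmin(t, 1)
    v <- c(pre, vstep, rep(-64, 0.05 * fs))
    tr <- Trace(v, fs, "mV", "step",
                list(amp = -200, onset = 0.05, offset = 0.25))
    s <- measureSag(tr)
    expect_lt(abs(s$sag - 10), 0.5)
    # pure RC response: no sag, no rebound
    tau <- 0.002
    vr <- c(pre, -64 - 16 * (1 - exp(-seq_len(stepN) / fs / tau)),
            -80 + 16 * (1 - exp(-seq_len(0.05 * fs) / fs / tau)))
    s0 <- measureSag(Trace(vr, fs, "mV", "step",
                           list(amp = -200, onset = 0.05, offset = 0.25)))
    expect_lt(s0$sag, 0.05)
    expect_false(s0$rebound)
})

test_that("PSC kinetics match closed forms and planted events are found", {
    fs <- 20000
    # near mono-exponential tail with tau_decay = 5 ms: decay_100_37 = tau
    t <- seq(0, 0.5, by = 1 / fs)
    k <- exp(-pmax(t - 0.1, 0) / 0.005) - exp(-pmax(t - 0.1, 0) / 1e-5)
    k[t < 0.1] <- 0
    tr <- Trace(60 * k, fs, "pA", "psc", list())
    d <- detectPSCs(tr)
    expect_lt(abs(d$ipsc$decay - 5) / 5, 0.02)
    expect_identical(d$epsc$n, 0L)        # outward-only train
    expect_true(d$ipsc$lowConfidence)     # single event
    # biexponential with finite rise: decay matches its closed form
    k2 <- exp(-pmax(t - 0.1, 0) / 0.005) - exp(-pmax(t - 0.1, 0) / 0.0005)
    k2[t < 0.1] <- 0
    d2 <- detectPSCs(Trace(60 * k2 / max(k2), fs, "pA", "psc", list()))
    expect_lt(abs(d2$ipsc$decay - biexpDecay(0.5, 5)) / biexpDecay(0.5, 5),
              0.05)
    # planted 2 Hz / 50 pA events on 3 pA noise: recall >= 0.95, amp +-10%
    cfg <- simConfig()
    sim <- simulateCounts(cfg, seed = 31)
    te <- trueEphys(sim$truth)
    cid <- te$cell[te$class == "Onset"][1]
    ts <- simulateTraces(cfg, sim$truth, cells = cid, protocols = "psc",
                         seed = 17)
    det <- detectPSCs(ts[[cid]][["psc"]])
    planted <- stimParams(ts[[cid]][["psc"]])
    recall <- mean(vapply(planted$epscTimes, function(tt)
        any(abs(det$epsc$times - tt) < 0.003), logical(1)))
    expect_gte(recall, 0.95)
    expect_lt(abs(det$epsc$amplitude - mean(planted$epscAmps)) /
              mean(planted$epscAmps), 0.1)
})

test_that("feature extraction is complete, deterministic, and NA-flagged", {
    nc <- noiselessCells()
    ct <- nc$ts[[nc$ids[["Onset"]]]]
    fv1 <- extractFeatureVector(ct)
    fv2 <- extractFeatureVector(ct)
    expect_identical(fv1, fv2)            # no RNG in extraction
    nonPSC <- setdiff(ephysFeatureNames(),
                      c("sepsc_amp", "sepsc_rise", "sepsc_decay",
                        "sipsc_amp", "sipsc_rise", "sipsc_decay"))
    expect_false(any(is.na(fv1[nonPSC])))
    # missing PSC protocol flags exactly the six synaptic fields
    expect_true(all(is.na(fv1[c("sepsc_amp", "sepsc_rise", "sepsc_decay",
                                "sipsc_amp", "sipsc_rise", "sipsc_decay")])))
    expect_identical(fv1$firing_class, "Onset")
})
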