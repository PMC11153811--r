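test_that("the same seed reproduces counts, truth and traces exactly", {
    cfg <- simConfig(nOnset = 4, nSustained = 2, nDelayed = 3,
                     nGenes = 120, nMarkersC1 = 15, nMarkersC2 = 8,
                     negcontrolN = 2)
    a <- simulateCounts(cfg, seed = 7)
    b <- simulateCounts(cfg, seed = 7)
    expect_identical(SummarizedExperiment::assay(a$sce, "counts"),
                     SummarizedExperiment::assay(b$sce, "counts"))
    expect_identical(trueLog2FC(a$truth), trueLog2FC(b$truth))
    expect_identical(trueEphys(a$truth), trueEphys(b$truth))
    ta <- simulateTraces(cfg, a$truth, cells = "cell_001",
                         protocols = c("rest", "step"), seed = 3)
    tb <- simulateTraces(cfg, b$truth, cells = "cell_001",
                         protocols = c("rest", "step"), seed = 3)
    expect_identical(traceSignal(ta[[1]][["step_-200"]]),
                     traceSignal(tb[[1]][["step_-200"]]))
    c3 <- simulateCounts(cfg, seed = 8)
    expect_false(identical(
        SummarizedExperiment::assay(a$sce, "counts"),
        SummarizedExperiment::assay(c3$sce, "counts")))
})

test_that("marker bookkeeping and config validation behave", {
    cfg0 <- simConfig(nOnset = 4, nSustained = 2, nDelayed = 3,
                      nGenes = 100, nMarkersC1 = 0, nMarkersC2 = 0)
    sim <- simulateCounts(cfg0, seed = 1)
    expect_true(all(geneDEFlag(sim$truth) == "none"))
    expect_true(all(trueLog2FC(sim$truth) == 0))
    # marker sets are disjoint and correctly sized
    sim2 <- defaultSim()
    expect_identical(sum(geneDEFlag(sim2$truth) == "up_c1"), 250L)
    expect_identical(sum(geneDEFlag(sim2$truth) == "up_c2"), 100L)
    expect_true(all(trueLog2FC(sim2$truth)[
        geneDEFlag(sim2$truth) == "up_c1"] >= 1))
    expect_true(all(trueLog2FC(sim2$truth)[
        geneDEFlag(sim2$truth) == "up_c2"] <= -1))
    # more markers than available genes is rejected
    expect_error(simConfig(nGenes = 100, nMarkersC1 = 80, nMarkersC2 = 40),
                 "marker")
    expect_error(simConfig(depthScale = 2), "depthScale")
})

test_that("empirical fold changes converge to the planted effects", {
    cfg <- simConfig(dropoutRate = 0, dispersion = 0,
                     libsizeLaw = list(sdlog = 0), negcontrolN = 0)
    sim <- simulateCounts(cfg, seed = 21)
    m <- as.matrix(SummarizedExperiment::assay(sim$sce, "counts"))
    cl <- trueCluster(sim$truth)
    emp <- log2(rowMeans(m[, cl == 1]) + 1e-9) -
           log2(rowMeans(m[, cl == 2]) + 1e-9)
    marker <- geneDEFlag(sim$truth) != "none" & trueBaseMean(sim$truth) >= 20
    dev <- emp[marker] - trueLog2FC(sim$truth)[marker]
    expect_gt(sum(marker), 20)
    expect_lt(max(abs(dev)), 0.2)
    expect_lt(mean(abs(dev)), 0.1)
})

test_that("negative controls are depth-scaled and marker directions hold", {
    sim <- defaultSim()
    m <- as.matrix(SummarizedExperiment::assay(sim$sce, "counts"))
    cls <- cellClass(sim$truth)
    ratio <- mean(colSums(m[, cls == "NegControl"])) /
             mean(colSums(m[, cls != "NegControl"]))
    expect_lt(abs(ratio - 1 / 8) / (1 / 8), 0.2)
    # planted markers sit on the correct side of ratio 1 in >= 95% of genes
    cl <- trueCluster(sim$truth)
    r <- (rowMeans(m[, !is.na(cl) & cl == 1]) + 0.01) /
         (rowMeans(m[, !is.na(cl) & cl == 2]) + 0.01)
    up1 <- geneDEFlag(sim$truth) == "up_c1"
    up2 <- geneDEFlag(sim$truth) == "up_c2"
    expect_gte(mean(r[up1] > 1), 0.95)
    expect_gte(mean(r[up2] < 1), 0.95)
})

test_that("transmitter gates reproduce the configured class frequencies", {
    sim <- defaultSim()
    m <- as.matrix(SummarizedExperiment::assay(sim$sce, "counts"))
    cls <- cellClass(sim$truth)
    pLSO <- cls %in% c("Onset", "Sustained")
    loc <- cls == "Delayed"
    se <- function(p, n) sqrt(p * (1 - p) / n)
    fr <- function(g, idx) mean(m[g, idx] > 0)
    expect_lt(abs(fr("Slc17a6", pLSO) - 0.66), 3 * se(0.66, sum(pLSO)))
    expect_lt(abs(fr("Calca", loc) - 0.93), 3 * se(0.93, sum(loc)) + 0.02)
    expect_lt(abs(fr("Ucn", loc) - 0.83), 3 * se(0.83, sum(loc)) + 0.02)
})

test_that("noiseless subthreshold responses equal the closed-form RC curve", {
    nc <- noiselessCells()
    te <- nc$te
    # LOC: pure RC (no sag component)
    cid <- nc$ids[["Delayed"]]
    tr <- nc$ts[[cid]][["step_-200"]]
    p <- te[cid, ]
    fs <- samplingRate(tr)
    sp <- stimParams(tr)
    idx <- (round(sp$onset * fs) + 1):round(sp$offset * fs)
    ts <- (seq_along(idx) - 1) / fs
    expected <- p$vRest - 200 * p$rIn / 1000 *
        (1 - exp(-ts / (p$tauM / 1000)))
    expect_lt(max(abs(traceSignal(tr)[idx] - expected)), 1e-9)
    # below-rheobase depolarizing step has no APs
    sub <- nc$ts[[cid]][["step_50"]]
    if (stimParams(sub)$amp < p$rheobase)
        expect_identical(nrow(detectAPs(sub)), 0L)
})

test_that("sag and rebound are class-specific", {
    nc <- noiselessCells()
    locSag <- measureSag(nc$ts[[nc$ids[["Delayed"]]]][["step_-200"]])
    expect_lt(locSag$sag, 0.2)
    expect_false(locSag$rebound)
    onSag <- measureSag(nc$ts[[nc$ids[["Onset"]]]][["step_-200"]])
    truthSag <- nc$te[nc$ids[["Onset"]], "sag"]
    expect_lt(abs(onSag$sag - truthSag) / truthSag, 0.05)
    expect_true(onSag$rebound)
})

test_that("onset cells fire the configured burst at the planted latency", {
    nc <- noiselessCells()
    cid <- nc$ids[["Onset"]]
    p <- nc$te[cid, ]
    st <- stepFamily(nc$ts[[cid]])
    amps <- vapply(st, function(t) stimParams(t)$amp, numeric(1))
    rheoGrid <- amps[amps >= p$rheobase][1]
    tr <- st[[which(amps == rheoGrid)]]
    aps <- detectAPs(tr, window = c(stimParams(tr)$onset,
                                    stimParams(tr)$offset))
    expect_identical(nrow(aps), 1L)
    expect_lt(abs(aps$latency[1] - p$latency), 0.05)
})

test_that("PSC traces carry planted events with class-specific kinetics", {
    cfg <- simConfig()
    sim <- simulateCounts(cfg, seed = 5)
    te <- trueEphys(sim$truth)
    idOn <- te$cell[te$class == "Onset"][1]
    idLoc <- te$cell[te$class == "Delayed"][1]
    ts <- simulateTraces(cfg, sim$truth, cells = c(idOn, idLoc),
                         protocols = "psc", noise = FALSE, seed = 2)
    dOn <- detectPSCs(ts[[idOn]][["psc"]])
    dLoc <- detectPSCs(ts[[idLoc]][["psc"]])
    expect_gt(dLoc$epsc$decay, dOn$epsc$decay)
    expect_gt(dLoc$ipsc$decay, dOn$ipsc$decay)
    # silent synapses give a flat noise trace
    cfg0 <- simConfig()
    for (cl in names(cfg0@ephysParams)) {
        cfg0@ephysParams[[cl]]$psc$epsc$rate <- 1e-9
        cfg0@ephysParams[[cl]]$psc$ipsc$rate <- 1e-9
    }
    ts0 <- simulateTraces(cfg0, sim$truth, cells = idOn,
                          protocols = "psc", seed = 2)
    sig <- traceSignal(ts0[[idOn]][["psc"]])
    expect_lt(abs(sd(sig) - cfg0@noiseSD$current), 0.5)
    d0 <- detectPSCs(ts0[[idOn]][["psc"]])
    expect_lt(d0$epsc$n + d0$ipsc$n, 5)
})

test_that("trace generation rejects invalid requests", {
    cfg <- simConfig(nOnset = 2, nSustained = 1, nDelayed = 1,
                     nGenes = 60, nMarkersC1 = 0, nMarkersC2 = 0,
                     negcontrolN = 1)
    sim <- simulateCounts(cfg, seed = 1)
    ctrl <- trueEphys(sim$truth)$cell[cellClass(sim$truth) == "NegControl"]
    expect_error(simulateTraces(cfg, sim$truth, cells = ctrl),
                 "negative controls")
    cfgLow <- simConfig(samplingRates = list(step = 1000, vc = 20000,
                                             psc = 20000, rest = 5000,
                                             triangle = 50000))
    expect_error(simulateTraces(cfgLow, sim$truth,
                                cells = "cell_001", protocols = "step"),
                 "sampling rate")
})
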