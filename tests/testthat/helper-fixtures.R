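# Shared fixtures, computed once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

.cached <- function(name, expr) {
    if (!exists(name, envir = .fixtures))
        assign(name, expr, envir = .fixtures)
    get(name, envir = .fixtures)
}

# default study-scale simulation (86 neurons + 4 controls, 2000 genes)
defaultSim <- function() .cached("defaultSim", simulateCounts(simConfig()))

# default simulation preprocessed with truth cluster labels
defaultPrep <- function() .cached("defaultPrep", {
    sim <- defaultSim()
    qc <- cellQCFilter(sim$sce)
    sce <- geneFilter(qc$sce)
    sce <- normalizeCounts(sce)
    sce <- computeTPM(sce)
    truthCl <- trueCluster(sim$truth)[match(colnames(sce),
                                            trueEphys(sim$truth)$cell)]
    list(sim = sim, qc = qc, sce = sce, truthCl = truthCl,
         norm = as.matrix(SingleCellExperiment::logcounts(sce)),
         tpm = as.matrix(SummarizedExperiment::assay(sce, "tpm")))
})

# DE table on the default prep against the true cluster labels
defaultDE <- function() .cached("defaultDE", {
    pp <- defaultPrep()
    differentialExpression(pp$norm, pp$tpm, pp$truthCl)
})

# a small planted two-cluster expression block for clustering tests
smallClusterData <- function() .cached("smallClusterData", {
    set.seed(99)
    n1 <- 18; n2 <- 12; g <- 150
    x <- matrix(rnorm(g * (n1 + n2)), g)
    x[1:40, seq_len(n1)] <- x[1:40, seq_len(n1)] + 4
    dimnames(x) <- list(sprintf("g%03d", seq_len(g)),
                        sprintf("c%02d", seq_len(n1 + n2)))
    list(x = x, truth = rep(1:2, c(n1, n2)))
})

# one noiseless neuron of each firing class with full trace protocols
noiselessCells <- function() .cached("noiselessCells", {
    cfg <- simConfig()
    sim <- simulateCounts(cfg, seed = 11)
    te <- trueEphys(sim$truth)
    ids <- vapply(c("Onset", "Sustained", "Delayed"),
                  function(cl) te$cell[te$class == cl][1], "")
    ts <- simulateTraces(cfg, sim$truth, cells = ids, noise = FALSE,
                         protocols = c("rest", "step", "vc_step"))
    list(cfg = cfg, truth = sim$truth, te = te, ids = ids, ts = ts)
})

# closed-form 100->37% decay time of a unit-peak biexponential
biexpDecay <- function(tauR, tauD) {
    tpk <- tauR * tauD / (tauD - tauR) * log(tauD / tauR)
    k <- function(t) exp(-t / tauD) - exp(-t / tauR)
    pk <- k(tpk)
    t37 <- uniroot(function(t) k(t) - 0.37 * pk,
                   c(tpk, tpk + 20 * tauD))$root
    t37 - tpk
}
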