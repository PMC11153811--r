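.toySCE <- function(m, lengths = NULL) {
    if (is.null(rownames(m))) rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
    if (is.null(colnames(m))) colnames(m) <- sprintf("c%02d", seq_len(ncol(m)))
    if (is.null(lengths)) lengths <- rep(1000L, nrow(m))
    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = m),
        rowData = S4Vectors::DataFrame(gene_id = rownames(m),
                                       length = lengths,
                                       row.names = rownames(m)))
}

test_that("MAD cell filter removes shallow libraries only", {
    m <- matrix(100L, 5, 10)
    expect_identical(sum(cellQCFilter(.toySCE(m))$report$removed), 0L)
    # 9 deep cells and 1 at 1/1000 depth: MAD of the log2 totals is 0, so
    # any strictly lower cell fails the median - 3 MAD rule
    m2 <- cbind(matrix(200000L, 5, 9), matrix(200L, 5, 1))
    qc <- cellQCFilter(.toySCE(m2))
    expect_identical(which(qc$report$removed), 10L)
    expect_identical(ncol(qc$sce), 9L)
    # default simulation: all four 1/8-depth negative controls flagged
    sim <- defaultSim()
    qcd <- cellQCFilter(sim$sce)
    ctrl <- trueEphys(sim$truth)$cell[cellClass(sim$truth) == "NegControl"]
    expect_true(all(qcd$report[ctrl, "removed"]))
    expect_error(cellQCFilter(.toySCE(m[, 1:3, drop = FALSE])), "4 cells")
})

test_that("gene filter applies the 5%-detection rule", {
    m <- matrix(0L, 4, 100)
    m[1, 1:4] <- 5L     # 4/100 cells: removed
    m[2, 1:5] <- 5L     # 5/100 cells: kept
    m[3, ] <- 2L        # ubiquitous: kept
    # row 4 all-zero: removed
    kept <- rownames(geneFilter(.toySCE(m)))
    expect_identical(kept, c("g02", "g03"))
    # dense matrix is untouched
    md <- matrix(3L, 6, 40)
    expect_identical(nrow(geneFilter(.toySCE(md))), 6L)
    # the alternative mean-count reading
    keptMean <- rownames(geneFilter(.toySCE(m), rule = "mean"))
    expect_identical(keptMean, "g03")
    m0 <- matrix(0L, 3, 100); m0[1, 1] <- 1L
    expect_error(geneFilter(.toySCE(m0)), "zero genes")
})

test_that("size factors: identity, scale equivariance, libsize concordance", {
    set.seed(4)
    # identical cells: all factors 1
    m <- matrix(rep(rpois(80, 20), 30), 80)
    expect_lt(max(abs(computeSizeFactors(.toySCE(m)) - 1)), 1e-8)
    # scale equivariance: a cell at exactly twice another's counts gets
    # exactly twice the factor (DE-free)
    v <- rpois(200, 15)
    m2 <- matrix(rep(v, 30), 200)
    m2[, 1] <- 2L * m2[, 1]
    sf2 <- computeSizeFactors(.toySCE(m2))
    expect_lt(abs(sf2[1] / sf2[2] - 2) / 2, 0.01)
    # deconvolution agrees with library size without composition effects
    base <- rlnorm(300, 1.5, 1)
    depth <- exp(rnorm(40, 0, 0.5))
    mu <- outer(base, depth)
    mm <- matrix(rnbinom(length(mu), mu = mu, size = 3), 300)
    sf <- computeSizeFactors(.toySCE(mm))
    expect_gt(cor(sf, colSums(mm)), 0.99)
    expect_lt(abs(exp(mean(log(sf))) - 1), 1e-10)
    # small cohorts fall back with a warning
    expect_warning(computeSizeFactors(.toySCE(mm[, 1:10])), "20 cells")
})

test_that("log-normalization arithmetic", {
    m <- matrix(c(0L, 3L, 6L, 0L), 2)
    sce <- normalizeCounts(.toySCE(m), sizeFactors = c(1, 2))
    lc <- SingleCellExperiment::logcounts(sce)
    expect_identical(lc[1, 1], 0)
    expect_identical(lc[2, 1], 2)
    expect_identical(lc[1, 2], 2)      # 6 / 2 + 1 = 4
    expect_error(normalizeCounts(.toySCE(m), sizeFactors = c(1, -1)),
                 "positive")
})

test_that("TPM normalizes for length and depth with exact column sums", {
    m <- matrix(c(10L, 10L), 2, 1)
    sce <- computeTPM(.toySCE(m, lengths = c(1000L, 2000L)))
    tpm <- SummarizedExperiment::assay(sce, "tpm")
    expect_equal(tpm[, 1], c(g01 = 2e6 / 3, g02 = 1e6 / 3), tolerance = 1e-9)
    # single-gene cell
    sce1 <- computeTPM(.toySCE(matrix(7L, 1, 1)))
    expect_equal(as.numeric(SummarizedExperiment::assay(sce1, "tpm")), 1e6)
    # column-sum invariant on simulated data
    pp <- defaultPrep()
    expect_lt(max(abs(colSums(pp$tpm) - 1e6)) / 1e6, 1e-6)
    mz <- matrix(c(1L, 0L), 1, 2)
    expect_error(computeTPM(.toySCE(mz)), "zero-count")
})

test_that("HVG selection ranks variable genes above the trend", {
    set.seed(8)
    n <- 60
    m <- matrix(rpois(300 * n, 20), 300)
    m[1, ] <- 20L                                  # constant gene
    m[2, ] <- as.integer(rep(c(0, 60), length.out = n))  # bimodal marker
    sce <- normalizeCounts(.toySCE(m), sizeFactors = rep(1, n))
    top <- selectHVGs(sce, n = 20)
    expect_false("g01" %in% top)
    expect_true("g02" %in% top)
    expect_identical(top[1], "g02")
    expect_setequal(selectHVGs(sce, n = 300), rownames(sce))
})

test_that("QC, gene filter and TPM commute with permutations", {
    sim <- simulateCounts(simConfig(nOnset = 8, nSustained = 4,
                                    nDelayed = 6, nGenes = 200,
                                    nMarkersC1 = 20, nMarkersC2 = 10),
                          seed = 3)
    sce <- sim$sce
    set.seed(12)
    pc <- sample(ncol(sce)); pg <- sample(nrow(sce))
    perm <- sce[pg, pc]
    f1 <- geneFilter(cellQCFilter(sce)$sce)
    f2 <- geneFilter(cellQCFilter(perm)$sce)
    expect_setequal(rownames(f1), rownames(f2))
    expect_setequal(colnames(f1), colnames(f2))
    t1 <- SummarizedExperiment::assay(computeTPM(f1), "tpm")
    t2 <- SummarizedExperiment::assay(computeTPM(f2), "tpm")
    expect_equal(t1, t2[rownames(t1), colnames(t1)], tolerance = 1e-12)
})
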