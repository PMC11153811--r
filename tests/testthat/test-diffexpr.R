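test_that("Welch tests: identical groups, symmetry, planted power", {
    x <- matrix(rep(c(1, 2, 3, 1, 2, 3), 5), 5, byrow = TRUE)
    dimnames(x) <- list(paste0("g", 1:5), paste0("c", 1:6))
    lab <- rep(1:2, each = 3)
    res <- welchTests(x, lab)
    expect_true(all(res$p_value == 1))
    expect_true(all(res$log2fc == 0))
    # label swap negates the fold change, p unchanged
    set.seed(3)
    y <- matrix(rnorm(50 * 20), 50)
    dimnames(y) <- list(paste0("g", 1:50), paste0("c", 1:20))
    l <- rep(1:2, each = 10)
    r1 <- welchTests(y, l)
    r2 <- welchTests(y, 3 - l)
    expect_equal(r1$log2fc, -r2$log2fc, tolerance = 1e-12)
    expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
    # planted strong markers at n = 56/30 are detected decisively
    de <- defaultDE()
    sim <- defaultSim()
    gi <- match(de$gene, rownames(sim$sce))
    strong <- geneDEFlag(sim$truth)[gi] != "none" &
        abs(trueLog2FC(sim$truth)[gi]) >= 2 &
        trueBaseMean(sim$truth)[gi] >= 5
    expect_gt(sum(strong), 20)
    expect_gte(mean(de$p_value[strong] < 1e-4), 0.95)
    expect_error(welchTests(y, rep(1, 20)), "two levels")
})

test_that("BH adjustment matches the hand-computed example", {
    expect_equal(bhAdjust(0.05), 0.05)
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)),
                 c(0.04, 0.04, 0.04, 0.04))
    expect_true(all(bhAdjust(rep(1, 10)) == 1))
})

test_that("rank-based AUROC equals the brute-force pairwise oracle", {
    bruteAUROC <- function(x, g1) {
        a <- x[g1]; b <- x[!g1]
        cmp <- outer(a, b, function(u, v)
            (u > v) + 0.5 * (u == v))
        mean(cmp)
    }
    set.seed(14)
    for (i in 1:100) {
        n <- sample(6:50, 1)
        n1 <- sample(3:(n - 3), 1)
        x <- matrix(sample(round(rnorm(2 * n), 1), n, replace = TRUE), 1)
        dimnames(x) <- list("g", paste0("c", 1:n))
        lab <- rep(2, n); lab[sample(n, n1)] <- 1
        expect_equal(unname(aurocScores(x, lab)),
                     bruteAUROC(x[1, ], lab == 1), tolerance = 1e-12)
    }
    # perfectly separated gene
    xs <- matrix(c(5, 6, 7, 1, 2, 3), 1)
    dimnames(xs) <- list("g", paste0("c", 1:6))
    expect_identical(unname(aurocScores(xs, rep(1:2, each = 3))), 1)
})

test_that("DEG calling applies inclusive boundaries and AUROC ranking", {
    de <- data.frame(gene = paste0("g", 1:4),
                     log2fc = c(1.0, 0.9, -2.0, 3.0),
                     fdr = c(0.05, 1e-9, 0.01, 0.2),
                     auroc = c(0.8, 0.99, 0.1, 0.9))
    out <- callDEGs(de)
    expect_identical(out$is_deg, c(TRUE, FALSE, TRUE, FALSE))
    expect_identical(out$deg_direction, c("up_c1", "none", "up_c2", "none"))
    expect_identical(out$deg_rank[1], 1L)
})

test_that("Super-DEG and similarity gates implement the TPM/FC rules", {
    de <- data.frame(gene = paste0("g", 1:6),
                     log2fc = c(5, 2.3, 1.58, 0.4, 0.3, 1.58),
                     fdr = c(1e-8, 1e-8, 1e-8, 0.5, 0.5, 0.5),
                     auroc = 0.9,
                     mean_tpm_c1 = c(1.5, 40, 12, 20, 8, 30),
                     mean_tpm_c2 = c(0.0, 8, 4, 15, 6, 10))
    de <- callDEGs(de)
    de <- callSuperDEGs(de)
    de <- callClusterSimilar(de)
    # the 1.5 vs 0.0 TPM DEG fails the >= 10 TPM gate
    expect_false(de$is_super_deg[1])
    expect_true(de$is_deg[1])
    expect_true(de$is_super_deg[2])          # 40 vs 8, FC >= 4
    expect_false(de$is_super_deg[3])         # FC < 4
    expect_true(de$is_cluster_similar[4])    # 20 vs 15, |lfc| <= 1
    expect_false(de$is_cluster_similar[5])   # below the TPM gate
    expect_false(de$is_cluster_similar[6])   # FC > 2
    # set-level invariants on the full simulated table
    full <- defaultDE()
    expect_true(all(full$is_deg[full$is_super_deg]))
    expect_false(any(full$is_deg & full$is_cluster_similar))
    expect_true(all(full$fdr >= 0 & full$fdr <= 1))
})

test_that("overlapping index: identity, separation, closed-form overlap", {
    set.seed(9)
    x <- rnorm(500)
    expect_equal(overlappingIndex(x, x), 1, tolerance = 1e-12)
    spread <- diff(range(x))
    expect_lte(overlappingIndex(x, x + 100 * spread), 0.01)
    # N(0,1) vs N(2,1): OI converges to 2*Phi(-1)
    a <- rnorm(5000); b <- rnorm(5000, 2)
    expect_lt(abs(overlappingIndex(a, b) - 2 * pnorm(-1)), 0.03)
    # symmetry and shift invariance
    u <- rexp(300); v <- rnorm(300, 1)
    expect_equal(overlappingIndex(u, v), overlappingIndex(v, u),
                 tolerance = 1e-12)
    expect_equal(overlappingIndex(u, v), overlappingIndex(u + 5, v + 5),
                 tolerance = 1e-9)
    # bounds over random instances
    for (i in 1:20) {
        p <- rnorm(40, sample(0:3, 1)); q <- rexp(40)
        oi <- overlappingIndex(p, q)
        expect_gte(oi, 0); expect_lte(oi, 1)
    }
    # degenerate point masses compare by equality
    expect_identical(overlappingIndex(rep(2, 5), rep(2, 3)), 1)
    expect_identical(overlappingIndex(rep(2, 5), rep(3, 3)), 0)
    expect_error(overlappingIndex(numeric(0), 1:3), "non-empty")
})

test_that("similarity ranking orders genes by OI with the 0.8 gate", {
    set.seed(41)
    n1 <- 15; n2 <- 15
    tpm <- rbind(
        same = c(rep(c(10, 12, 14), length.out = n1),
                 rep(c(10, 12, 14), length.out = n2)),
        near = c(rnorm(n1, 20, 3), rnorm(n2, 21, 3)),
        far = c(rnorm(n1, 50, 2), rnorm(n2, 11, 2)))
    colnames(tpm) <- paste0("c", seq_len(n1 + n2))
    labels <- rep(1:2, c(n1, n2))
    de <- data.frame(gene = rownames(tpm), is_cluster_similar = TRUE)
    rs <- rankSimilarity(de, tpm, labels)
    expect_identical(rs$gene[1], "same")
    expect_equal(rs$oi[1], 1, tolerance = 1e-9)
    expect_identical(rs$gene[3], "far")
    expect_lt(rs$oi[3], 0.2)
    # toy threshold arithmetic: OI {0.95, 0.85, 0.6} keeps 2 at 0.8
    expect_identical(sum(c(0.95, 0.85, 0.6) >= 0.8), 2L)
    expect_identical(sum(rs$high_stringency), sum(rs$oi >= 0.8))
})

test_that("expression intersection splits genes at the TPM threshold", {
    c1 <- c(a = 1200, b = 1200, c = 100, d = 2000)
    c2 <- c(a = 1100, b = 300, c = 1500, d = 900)
    r <- expressionIntersection(c1, c2)
    expect_identical(r$intersection, "a")
    expect_identical(r$exclusive_c1, c("b", "d"))
    expect_identical(r$exclusive_c2, "c")
    rHigh <- expressionIntersection(c1, c2, threshold = 1e7)
    expect_identical(lengths(rHigh), c(intersection = 0L,
                                       exclusive_c1 = 0L,
                                       exclusive_c2 = 0L))
    expect_error(expressionIntersection(c1, c2, threshold = 0), "positive")
})

test_that("permuted labels produce no excess discoveries", {
    pp <- defaultPrep()
    set.seed(77)
    fracs <- vapply(1:20, function(i) {
        lab <- sample(pp$truthCl)
        res <- welchTests(pp$norm, lab)
        mean(bhAdjust(res$p_value) <= 0.05)
    }, numeric(1))
    se <- sqrt(0.05 * 0.95 / nrow(pp$norm))
    expect_lte(mean(fracs), 0.05 + 3 * se)
})
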