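test_that("pearsonWithP handles exact, reversed and degenerate inputs", {
    expect_equal(pearsonWithP(1:5, 1:5)$r, 1)
    expect_equal(pearsonWithP(1:5, 1:5)$p, 1e-300)   # |r| = 1 floors p
    expect_equal(pearsonWithP(c(1, 2, 3), c(3, 2, 1))$r, -1)
    expect_false(pearsonWithP(c(1, 2, NA), c(1, NA, 2))$usable)  # n < 3
    expect_false(pearsonWithP(rep(1, 5), 1:5)$usable)            # zero var
    # pairwise deletion drops exactly the incomplete positions
    res <- pearsonWithP(c(1, 2, 3, 4, NA, 6), c(1.2, NA, 2.8, 4.4, 5, 6.1))
    expect_equal(res$n_used, 4L)
    expect_true(res$usable)
})

test_that("r and p match direct-formula and library oracles on a worked fixture", {
    x <- c(0.12, 1.40, -0.73, 2.10, 0.55, -1.22, 0.98, 1.75, -0.31, 0.04)
    y <- c(0.35, 1.10, -0.20, 1.65, 0.90, -0.85, 0.40, 2.05, 0.12, -0.44)
    got <- pearsonWithP(x, y)
    orc <- oraclePearson(x, y)
    expect_equal(got$r, orc$r, tolerance = 1e-12)
    expect_equal(got$p, orc$p, tolerance = 1e-12)
    ct <- cor.test(x, y)
    expect_equal(got$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(got$p, ct$p.value, tolerance = 1e-12)
})

test_that("r is affine-invariant and flips sign under negative scaling", {
    set.seed(33)
    for (i in 1:10) {
        x <- rnorm(30)
        y <- rnorm(30)
        r0 <- pearsonWithP(x, y)$r
        a <- runif(1, -5, 5); b <- runif(1, 0.1, 10)
        expect_equal(pearsonWithP(a + b * x, y)$r, r0, tolerance = 1e-12)
        expect_equal(pearsonWithP(-b * x, y)$r, -r0, tolerance = 1e-12)
    }
})

test_that("gene-map correlation agrees with the scalar primitive and cor.test", {
    cfg <- smallConfig(expressionMissingRate = 0.15)
    sim <- simulateStudy(cfg)
    map <- effectMap(sim$cohort, DiagnosisContrast("AD"))
    res <- suppressMessages(correlateGenes(sim$expr, map))
    y <- as.data.frame(map)$neglog10p
    names(y) <- roiLabels(map)
    E <- exprMatrix(sim$expr)[, names(y), drop = FALSE]
    for (i in sample(nrow(res), 12)) {
        g <- res$gene[i]
        sc <- pearsonWithP(E[g, ], y)
        expect_equal(res$r[i], sc$r, tolerance = 1e-12)
        expect_equal(res$n_used[i], sc$n_used)
        expect_equal(res$p[i], sc$p, tolerance = 1e-12)
        ok <- !is.na(E[g, ])
        ct <- cor.test(E[g, ok], y[ok])
        expect_equal(res$p[i], ct$p.value, tolerance = 1e-10)
    }
})

test_that("a gene identical to the significance map correlates perfectly", {
    sim <- generateCohort(smallConfig())
    map <- effectMap(sim$cohort, DiagnosisContrast(c("LMCI", "AD")))
    y <- as.data.frame(map)$neglog10p
    m <- rbind(PERFECT = y,
               NOISE = rnorm(length(y)))
    colnames(m) <- roiLabels(map)
    res <- correlateGenes(RegionalExpression(m), map)
    expect_equal(res$r[res$gene == "PERFECT"], 1)
    expect_equal(res$p[res$gene == "PERFECT"], 1e-300)
})

test_that("zero-variance and sparse genes are excluded, not zeroed", {
    sim <- generateCohort(smallConfig())
    map <- effectMap(sim$cohort, DiagnosisContrast("AD"))
    R <- length(roiLabels(map))
    m <- rbind(FLAT = rep(2.5, R),
               OK = rnorm(R),
               SPARSE = c(rnorm(3), rep(NA, R - 3)))
    colnames(m) <- roiLabels(map)
    expr <- RegionalExpression(m)
    expect_message(res <- correlateGenes(expr, map), "unusable")
    expect_setequal(res$gene, c("OK", "SPARSE"))  # 3 pairs is still usable
    expect_false("FLAT" %in% res$gene)

    mm <- m
    colnames(mm) <- paste0("L_other", seq_len(R), "_ROI")
    expect_error(correlateGenes(RegionalExpression(mm), map), "share 0 ROI")
})

test_that("Bonferroni adjustment uses the pooled family actually tested", {
    one <- S4Vectors::DataFrame(gene = "G1", contrast = "CN_vs_AD",
                                r = 0.5, n_used = 100L, p = 0.01)
    adj <- suppressMessages(bonferroniFamily(one, alpha = 0.05))
    expect_equal(adj$p_adjusted, 0.01)     # family of one is the identity
    expect_equal(adj@familySize, 1L)

    ten <- S4Vectors::DataFrame(gene = sprintf("G%d", 1:10),
                                contrast = "CN_vs_AD", r = 0.1,
                                n_used = 100L, p = rep(0.2, 10))
    adj10 <- suppressMessages(bonferroniFamily(ten))
    expect_true(all(adj10$p_adjusted == 1))  # capped at 1

    # matches stats::p.adjust on random families, and is monotone, >= p
    set.seed(4)
    p <- runif(200)
    df <- S4Vectors::DataFrame(gene = sprintf("G%d", 1:200),
                               contrast = "CN_vs_AD", r = 0,
                               n_used = 50L, p = p)
    adj200 <- suppressMessages(bonferroniFamily(df))
    expect_equal(adj200$p_adjusted, p.adjust(p, "bonferroni"))
    expect_true(all(adj200$p_adjusted >= p))
    expect_identical(order(adj200$p_adjusted[order(p)]), seq_len(200))

    expect_error(bonferroniFamily(list()), "no correlation results")
    expect_error(bonferroniFamily(df, alpha = 1.2), "alpha")
})

test_that("the per-contrast family option adjusts within each contrast", {
    df <- S4Vectors::DataFrame(
        gene = rep(c("G1", "G2"), 2),
        contrast = rep(c("CN_vs_AD", "CN_vs_EMCI"), each = 2),
        r = 0.2, n_used = 50L, p = c(0.01, 0.02, 0.03, 0.04))
    adj <- suppressMessages(bonferroniFamily(df, family = "per-contrast"))
    expect_equal(adj$p_adjusted, c(0.02, 0.04, 0.06, 0.08))
})

test_that("the across-contrast intersection keeps only 6/6-significant genes", {
    mk <- function(gene, contrast, sig)
        S4Vectors::DataFrame(gene = gene, contrast = contrast, r = 0.5,
                             n_used = 100L, p = 1e-9,
                             p_adjusted = ifelse(sig, 1e-4, 0.5),
                             significant = sig)
    cns <- vapply(buildContrasts(), contrastName, character(1))
    allSix <- do.call(rbind, lapply(cns, function(cn)
        mk(c("AQP9", "SPRN"), cn, sig = c(TRUE, cn != "CN_vs_AD"))))
    hits <- intersectAcrossContrasts(allSix)
    expect_identical(hits, "AQP9")       # SPRN is 5/6 -> excluded
    expect_identical(intersectAcrossContrasts(allSix[0, ]), character(0))
})

test_that("intersection output is a subset of every contrast's significant set", {
    res <- simulateStudy(smallConfig(
        groupSizes = c(CN = 120, EMCI = 120, LMCI = 120, AD = 120),
        nRois = 120, effectSizes = c(EMCI = .15, LMCI = .25, AD = .35),
        signalRTarget = 0.75, nGenes = 200))
    maps <- lapply(buildContrasts(), function(ct) effectMap(res$cohort, ct))
    adj <- suppressMessages(bonferroniFamily(
        lapply(maps, function(m) correlateGenes(res$expr, m))))
    hits <- intersectAcrossContrasts(adj)
    df <- as.data.frame(adj)
    for (cn in unique(df$contrast)) {
        sigSet <- df$gene[df$contrast == cn & df$significant]
        expect_true(all(hits %in% sigSet))
    }
})

test_that("annotation partitioning is a disjoint, case-insensitive split", {
    p <- partitionByAnnotation(c("AQP9", "SPRN"), known = "AQP9")
    expect_identical(p$known, "AQP9")
    expect_identical(p$novel, "SPRN")
    p2 <- partitionByAnnotation(c("aqp9", "Ngb"), known = c("AQP9", "NGB"))
    expect_identical(p2$known, c("AQP9", "NGB"))
    expect_length(p2$novel, 0L)
    p3 <- partitionByAnnotation(c("B", "A"), known = character(0))
    expect_identical(p3$novel, c("A", "B"))
    expect_length(intersect(p$known, p$novel), 0L)
})

test_that("noise-gene correlations follow the null t-transform distribution", {
    cfg <- smallConfig(nGenes = 400, nSignalGenes = 0, nRois = 60,
                       effectSizes = c(EMCI = 0, LMCI = 0, AD = 0),
                       seed = 77)
    sim <- simulateStudy(cfg)
    map <- effectMap(sim$cohort, DiagnosisContrast("AD"))
    res <- correlateGenes(sim$expr, map)
    # under the null, p-values are uniform: Q-Q agreement via KS
    expect_gt(ks.test(res$p, "punif")$p.value, 0.01)
})
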