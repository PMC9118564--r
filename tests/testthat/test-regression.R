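test_that("the per-ROI fit matches the explicit normal-equations oracle", {
    # hand-chosen 8-subject worked fixture: 4 CN / 4 case
    ph <- data.frame(
        subject_id = sprintf("w%d", 1:8),
        diagnosis = rep(c("CN", "AD"), each = 4),
        age = c(66, 72, 75, 81, 64, 70, 77, 85),
        sex = c(1, 0, 1, 0, 0, 1, 0, 1),
        education = c(12, 16, 18, 14, 20, 13, 17, 15))
    trait <- c(1.02, 1.11, 1.08, 1.21, 1.35, 1.28, 1.41, 1.52)
    des <- assembleDesign(ph, DiagnosisContrast("AD"))
    fit <- fitRoiRegression(des, trait)
    orc <- oracleOls(des$X, trait)
    expect_equal(fit$beta, orc$beta, tolerance = 1e-10)
    expect_equal(fit$se, orc$se, tolerance = 1e-10)
    expect_equal(fit$t, orc$t, tolerance = 1e-10)
    expect_equal(fit$p, orc$p, tolerance = 1e-10)

    # and across many random designs/traits
    set.seed(101)
    for (i in 1:20) {
        n <- sample(12:40, 1)
        phr <- data.frame(subject_id = as.character(seq_len(n)),
                          diagnosis = sample(c("CN", "AD"), n, TRUE,
                                             prob = c(.5, .5)),
                          age = runif(n, 55, 95), sex = rbinom(n, 1, .5),
                          education = runif(n, 6, 20))
        if (length(unique(phr$diagnosis)) < 2) next
        d <- assembleDesign(phr, DiagnosisContrast("AD"))
        y <- rnorm(n)
        f <- fitRoiRegression(d, y)
        o <- oracleOls(d$X, y)
        expect_equal(f$t, o$t, tolerance = 1e-10)
        expect_equal(f$p, o$p, tolerance = 1e-10)
    }
})

test_that("fit statistics also agree with stats::lm as a library cross-check", {
    set.seed(7)
    ph <- data.frame(subject_id = as.character(1:30),
                     diagnosis = rep(c("CN", "LMCI"), 15),
                     age = runif(30, 55, 95), sex = rbinom(30, 1, .5),
                     education = runif(30, 6, 20))
    y <- rnorm(30, 1.1, 0.2)
    des <- assembleDesign(ph, DiagnosisContrast("LMCI"))
    fit <- fitRoiRegression(des, y)
    lmc <- summary(lm(y ~ dx + age + sex + education,
                      data = data.frame(dx = des$X[, "diagnosis"],
                                        age = des$X[, "age"],
                                        sex = des$X[, "sex"],
                                        education = des$X[, "education"])))
    expect_equal(fit$beta, lmc$coefficients["dx", 1], tolerance = 1e-12)
    expect_equal(fit$p, lmc$coefficients["dx", 4], tolerance = 1e-12)
})

test_that("design assembly pools cases, excludes other stages, and fails fast", {
    cfg <- syntheticConfig(seed = 5, nRois = 5, nGenes = 10,
                           nSignalGenes = 0)
    cohort <- generateCohort(cfg)$cohort
    des <- assembleDesign(cohort, DiagnosisContrast(c("EMCI", "LMCI")))
    expect_equal(nrow(des$X), 255 + 296 + 218)   # CN + EMCI + LMCI
    expect_setequal(unique(des$X[, "diagnosis"]), c(0, 1))

    noAD <- toyPhenotypes()[1:3, ]
    expect_error(assembleDesign(noAD, DiagnosisContrast("AD")), "no case")
    allCN <- data.frame(subject_id = as.character(1:10),
                        diagnosis = "CN", age = 70, sex = 1, education = 16)
    expect_error(assembleDesign(allCN, DiagnosisContrast("AD")), "no case")
    allAD <- transform(allCN, diagnosis = "AD")
    expect_error(assembleDesign(allAD, DiagnosisContrast("AD")), "no control")
    tiny <- data.frame(subject_id = as.character(1:5),
                       diagnosis = c("CN", "CN", "AD", "AD", "AD"),
                       age = 70:74, sex = c(0, 1, 0, 1, 0), education = 12:16)
    expect_error(assembleDesign(tiny, DiagnosisContrast("AD")), "fewer than")
})

test_that("a perfect fit floors p instead of producing infinities", {
    set.seed(3)
    ph <- data.frame(subject_id = as.character(1:20),
                     diagnosis = rep(c("CN", "AD"), 10),
                     age = runif(20, 55, 95), sex = rbinom(20, 1, .5),
                     education = runif(20, 6, 20))
    des <- assembleDesign(ph, DiagnosisContrast("AD"))
    y <- des$X[, "diagnosis"]            # trait equals the indicator
    fit <- fitRoiRegression(des, y)
    expect_equal(fit$beta, 1, tolerance = 1e-10)
    expect_equal(fit$p, 1e-300)
    expect_true(is.finite(-log10(fit$p)))
})

test_that("diagnosis inference is invariant to affine changes of covariates", {
    set.seed(11)
    ph <- data.frame(subject_id = as.character(1:60),
                     diagnosis = rep(c("CN", "AD"), 30),
                     age = runif(60, 55, 95), sex = rbinom(60, 1, .5),
                     education = runif(60, 6, 20))
    y <- rnorm(60)
    base <- fitRoiRegression(assembleDesign(ph, DiagnosisContrast("AD")), y)
    shifted <- transform(ph, age = age + 100, education = education * 3.7)
    alt <- fitRoiRegression(assembleDesign(shifted, DiagnosisContrast("AD")), y)
    expect_equal(alt$t, base$t, tolerance = 1e-10)
    expect_equal(alt$p, base$p, tolerance = 1e-10)
})

test_that("rank-deficient designs are rejected naming the collinear column", {
    set.seed(2)
    ph <- data.frame(subject_id = as.character(1:20),
                     diagnosis = rep(c("CN", "AD"), 10),
                     age = runif(20, 55, 95), sex = rbinom(20, 1, .5),
                     education = runif(20, 6, 20))
    des <- assembleDesign(ph, DiagnosisContrast("AD"))
    des$X[, "education"] <- 2 * des$X[, "age"]   # force collinearity
    expect_error(fitRoiRegression(des, rnorm(20)),
                 "collinear.*(education|age)")
})

test_that("the t-based p matches an empirical permutation null", {
    set.seed(21)
    n <- 60
    dx <- rep(c(0, 1), each = n / 2)
    ph <- data.frame(subject_id = as.character(1:n),
                     diagnosis = ifelse(dx == 1, "AD", "CN"),
                     age = runif(n, 55, 95), sex = rbinom(n, 1, .5),
                     education = runif(n, 6, 20))
    y <- 0.07 * dx + rnorm(n, 0, 0.2)    # modest effect -> mid-range p
    des <- assembleDesign(ph, DiagnosisContrast("AD"))
    obs <- fitRoiRegression(des, y)
    B <- 1000
    tPerm <- replicate(B, {
        d2 <- des
        d2$X[, "diagnosis"] <- sample(d2$X[, "diagnosis"])
        fitRoiRegression(d2, y)$t
    })
    pEmp <- mean(abs(tPerm) >= abs(obs$t))
    se <- sqrt(obs$p * (1 - obs$p) / B)
    expect_lt(abs(pEmp - obs$p), 2 * se + 1e-12)
})

test_that("effect maps cover the ROI subset, sort by label, and rank by significance", {
    cfg <- smallConfig(affectedRoiFraction = 0.4,
                       effectSizes = c(EMCI = 0.2, LMCI = 0.3, AD = 0.4),
                       groupSizes = c(CN = 80, EMCI = 80, LMCI = 80, AD = 80))
    sim <- generateCohort(cfg)
    sub <- sample(roiLabels(sim$cohort), 25)
    map <- effectMap(sim$cohort, DiagnosisContrast("AD"), roiSubset = sub)
    expect_equal(nrow(as.data.frame(map)), 25L)
    expect_identical(roiLabels(map), sort(sub, method = "radix"))

    # neglog10p is strictly decreasing in p
    st <- as.data.frame(map)
    expect_identical(order(st$p), order(-st$neglog10p))

    # affected ROIs dominate the significance ranking (rank-sum test)
    full <- effectMap(sim$cohort, DiagnosisContrast("AD"))
    stf <- as.data.frame(full)
    aff <- stf$roi_label %in% sim$truth@affectedRois
    wt <- wilcox.test(stf$neglog10p[aff], stf$neglog10p[!aff],
                      alternative = "greater", exact = FALSE)
    expect_lt(wt$p.value, 0.01)

    expect_error(effectMap(sim$cohort, DiagnosisContrast("AD"),
                           roiSubset = c("L_nope_ROI")), "not in the cohort")
})

test_that("ROI thresholding supports raw and Bonferroni criteria", {
    map <- toyEffectMap(c(0.001, 0.04, 0.2))
    expect_length(suppressMessages(significantRois(map, 0.05, "none")), 2L)
    expect_length(suppressMessages(significantRois(map, 0.05, "bonferroni")),
                  1L)
    expect_error(significantRois(map, 1.5), "alpha")
    expect_error(significantRois(map, 0), "alpha")
})
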