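# Shared fixtures and independent oracles for the suite.

# tiny phenotype table, one subject per diagnostic group
toyPhenotypes <- function() {
    data.frame(subject_id = c("s1", "s2", "s3", "s4"),
               diagnosis = c("CN", "EMCI", "LMCI", "AD"),
               age = c(70.5, 68.2, 75.0, 80.1),
               sex = c(1, 0, 1, 0),
               education = c(16, 12, 18, 14))
}

writeCsv <- function(df, path = tempfile(fileext = ".csv")) {
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    path
}

# a small but well-conditioned synthetic study
smallConfig <- function(...) {
    args <- list(groupSizes = c(CN = 30, EMCI = 30, LMCI = 30, AD = 30),
                 nRois = 40, nGenes = 120, nSignalGenes = 4,
                 nKnownGenes = 20, expressionMissingRate = 0, seed = 42)
    over <- list(...)
    args[names(over)] <- over
    do.call(syntheticConfig, args)
}

# independent OLS oracle: explicit normal equations by matrix inversion
oracleOls <- function(X, y) {
    XtX <- t(X) %*% X
    b <- solve(XtX) %*% t(X) %*% y
    res <- y - X %*% b
    df <- nrow(X) - ncol(X)
    s2 <- sum(res^2) / df
    se <- sqrt(s2 * diag(solve(XtX)))
    j <- which(colnames(X) == "diagnosis")
    tstat <- unname(b[j] / se[j])
    list(beta = unname(b[j]), se = unname(se[j]), t = tstat,
         p = 2 * pt(abs(tstat), df, lower.tail = FALSE))
}

# independent Pearson oracle: direct sums of squares / cross-products,
# t-tail by numerical integration of the t density
oraclePearson <- function(x, y) {
    n <- length(x)
    sx <- sum(x); sy <- sum(y)
    num <- n * sum(x * y) - sx * sy
    den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
    r <- num / den
    df <- n - 2
    tstat <- abs(r) * sqrt(df) / sqrt(1 - r^2)
    tail <- integrate(function(u) dt(u, df), tstat, Inf,
                      rel.tol = 1e-12)$value
    list(r = r, p = 2 * tail)
}

# build an EffectMap by hand from a p-value vector
toyEffectMap <- function(p, labels = sprintf("L_T%02d_ROI", seq_along(p)),
                         cases = "AD") {
    methods::new("EffectMap",
        contrast = DiagnosisContrast(cases),
        stats = S4Vectors::DataFrame(
            roi_label = labels, beta = seq_along(p) / 10,
            se = rep(0.1, length(p)), t = qnorm(1 - p / 2),
            p = p, neglog10p = -log10(p)),
        nSubjects = 100L)
}
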