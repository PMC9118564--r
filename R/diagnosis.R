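#' @include AllClasses.R AllGenerics.R
NULL

## p-values are floored here before any -log10 so perfect fits yield a
## finite, rank-preserving significance instead of Inf.
.P_FLOOR <- 1e-300

#' Enumerate stage-contiguous diagnostic contrasts
#'
#' Builds every case-control comparison of CN against a non-empty
#' contiguous run of the progression-ordered case stages. Because the
#' disease progresses EMCI -> LMCI -> AD, pooling EMCI with AD while
#' skipping LMCI would mix non-adjacent severity stages, so that
#' combination is never emitted. Over the full stage set this yields
#' six contrasts: CN vs EMCI, CN vs LMCI, CN vs AD, CN vs EMCI+LMCI,
#' CN vs LMCI+AD, and CN vs EMCI+LMCI+AD.
#'
#' @param stages Ordered case stages; default the full progression
#'   `c("EMCI", "LMCI", "AD")`.
#' @return List of [DiagnosisContrast-class], singletons first, then
#'   pairs, then the full pool, each in progression order.
#' @export
#' @examples
#' vapply(buildContrasts(), contrastName, character(1))
buildContrasts <- function(stages = c("EMCI", "LMCI", "AD")) {
    if (length(stages) == 0L) stop("stage list is empty")
    if (!all(stages %in% .CASE_STAGES) ||
        is.unsorted(match(stages, .CASE_STAGES), strictly = TRUE))
        stop("stages must be an ordered subset of EMCI < LMCI < AD")
    k <- length(stages)
    out <- list()
    for (len in seq_len(k))
        for (start in seq_len(k - len + 1L))
            out[[length(out) + 1L]] <-
                DiagnosisContrast(stages[start:(start + len - 1L)])
    out
}

#' Assemble the regression design for one contrast
#'
#' Subjects outside the contrast's control and case groups are
#' excluded. The diagnosis predictor is a single binary indicator
#' (1 for any pooled case stage, 0 for control); age, sex and education
#' enter as continuous covariates alongside an intercept.
#'
#' @param x An [ImagingCohort-class] or a phenotype `data.frame` as
#'   returned by [readPhenotypes()].
#' @param contrast A [DiagnosisContrast-class].
#' @return List with `X` (n x 5 design matrix, columns `(Intercept)`,
#'   `diagnosis`, `age`, `sex`, `education`), `subjectIds` (row-aligned),
#'   and `contrast`.
#' @export
assembleDesign <- function(x, contrast) {
    stopifnot(is(contrast, "DiagnosisContrast"))
    if (is(x, "ImagingCohort")) {
        cd <- colData(x)
        ph <- data.frame(subject_id = rownames(cd),
                         diagnosis = as.character(cd$diagnosis),
                         age = cd$age, sex = cd$sex, education = cd$education)
    } else ph <- x
    dx <- as.character(ph$diagnosis)
    keep <- dx %in% c(contrast@control, contrast@cases)
    ph <- ph[keep, , drop = FALSE]
    dx <- dx[keep]
    if (!any(dx == contrast@control))
        stop("no control (", contrast@control, ") subjects for ",
             contrast@name)
    if (!any(dx %in% contrast@cases))
        stop("no case subjects for ", contrast@name)
    X <- cbind(`(Intercept)` = 1,
               diagnosis = as.numeric(dx %in% contrast@cases),
               age = as.numeric(ph$age), sex = as.numeric(ph$sex),
               education = as.numeric(ph$education))
    if (nrow(X) < ncol(X) + 2L)
        stop("fewer than ", ncol(X) + 2L, " usable subjects for ",
             contrast@name)
    list(X = X, subjectIds = as.character(ph$subject_id),
         contrast = contrast)
}

## QR-based OLS for one design against one or many trait columns.
## Returns per-column diagnosis-coefficient statistics.
.olsDiagnosis <- function(X, Y) {
    Y <- as.matrix(Y)
    stopifnot(nrow(Y) == nrow(X))
    qrX <- qr(X)
    p <- ncol(X)
    if (qrX$rank < p) {
        bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
        stop("rank-deficient design; collinear column(s): ",
             paste(bad, collapse = ", "))
    }
    B <- qr.coef(qrX, Y)
    res <- qr.resid(qrX, Y)
    df <- nrow(X) - p
    sigma2 <- colSums(res^2) / df
    XtXinv <- chol2inv(qr.R(qrX))
    unpivot <- order(qrX$pivot)
    j <- which(colnames(X) == "diagnosis")
    vDiag <- XtXinv[unpivot, unpivot, drop = FALSE][j, j]
    beta <- B[j, ]
    se <- sqrt(sigma2 * vDiag)
    t <- ifelse(se > 0, beta / se, sign(beta) * Inf)
    pval <- pmax(2 * stats::pt(abs(t), df, lower.tail = FALSE), .P_FLOOR)
    data.frame(beta = unname(beta), se = unname(se), t = unname(t),
               p = unname(pval), row.names = colnames(Y))
}

#' Fit the per-ROI diagnostic regression
#'
#' Ordinary least squares of one (or several) imaging-trait vectors on
#' the contrast design; reports the diagnosis coefficient with
#' `t = beta / se` and a two-sided p-value from the t distribution on
#' `n - p` degrees of freedom. A perfect fit (zero residual variance)
#' yields `t = +/-Inf` and `p` at the numerical floor 1e-300.
#'
#' @param design Output of [assembleDesign()].
#' @param trait Numeric vector (one ROI) or n x k matrix (k ROIs),
#'   rows aligned with `design$subjectIds`; all values finite.
#' @return `data.frame` with columns `beta`, `se`, `t`, `p`, one row
#'   per trait column.
#' @export
fitRoiRegression <- function(design, trait) {
    trait <- as.matrix(trait)
    if (any(!is.finite(trait))) stop("trait values must be finite")
    if (nrow(trait) != nrow(design$X))
        stop("trait length does not match the design (",
             nrow(trait), " vs ", nrow(design$X), ")")
    .olsDiagnosis(design$X, trait)
}

#' Compute the imaging-diagnosis map for one contrast
#'
#' Runs the covariate-adjusted regression independently for every ROI
#' in `roiSubset` and assembles the significance map: per-ROI `beta`,
#' `se`, `t`, two-sided `p`, and `neglog10p = -log10(p)` (the rendering
#' used for brain significance maps). Records are sorted by ROI label.
#'
#' @param cohort An [ImagingCohort-class].
#' @param contrast A [DiagnosisContrast-class].
#' @param roiSubset ROI labels to analyze; defaults to the left
#'   hemisphere of the cohort's atlas (see [filterHemisphere()]).
#' @return An [EffectMap-class].
#' @export
effectMap <- function(cohort, contrast,
                      roiSubset = filterHemisphere(roiLabels(cohort))) {
    stopifnot(is(cohort, "ImagingCohort"))
    bad <- setdiff(roiSubset, roiLabels(cohort))
    if (length(bad))
        stop("ROI(s) not in the cohort: ",
             paste(utils::head(bad, 5L), collapse = ", "))
    if (length(roiSubset) == 0L) stop("empty ROI subset")
    des <- assembleDesign(cohort, contrast)
    Y <- t(traitMatrix(cohort)[roiSubset, des$subjectIds, drop = FALSE])
    fit <- tryCatch(.olsDiagnosis(des$X, Y),
                    error = function(e) stop("effect map for ",
                        contrast@name, ": ", conditionMessage(e),
                        call. = FALSE))
    ord <- order(roiSubset, method = "radix")
    st <- DataFrame(roi_label = roiSubset[ord],
                    beta = fit$beta[ord], se = fit$se[ord],
                    t = fit$t[ord], p = fit$p[ord],
                    neglog10p = -log10(fit$p[ord]))
    new("EffectMap", contrast = contrast, stats = st,
        nSubjects = nrow(des$X))
}

#' ROIs with a significant diagnostic effect
#'
#' Thresholds an imaging-diagnosis map at `alpha`, either on raw
#' p-values (default) or with Bonferroni correction over the map's ROI
#' family (`alpha / nROI`). The threshold choice is reported via
#' `message()` because published ROI counts depend on it.
#'
#' @param map An [EffectMap-class].
#' @param alpha Significance level in (0, 1).
#' @param correction `"none"` (raw p < alpha) or `"bonferroni"`.
#' @return Character vector of significant ROI labels (map order).
#' @export
significantRois <- function(map, alpha = 0.05,
                            correction = c("none", "bonferroni")) {
    stopifnot(is(map, "EffectMap"))
    correction <- match.arg(correction)
    if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
        stop("alpha must lie in (0, 1)")
    thr <- if (correction == "bonferroni") alpha / nrow(map@stats) else alpha
    message("ROI significance for ", map@contrast@name, ": ", correction,
            " threshold p < ", format(thr))
    map@stats$roi_label[map@stats$p < thr]
}
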