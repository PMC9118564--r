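#' @include AllClasses.R AllGenerics.R diagnosis.R
NULL

## two-sided p for a Pearson r at n points via the t transform,
## vectorized; |r| = 1 (zero residual) hits the same 1e-300 floor as
## the regression p-values.
.pearsonP <- function(r, n) {
    r <- pmin(1, pmax(-1, r))
    df <- n - 2L
    t <- abs(r) * sqrt(df) / sqrt(pmax(1 - r^2, 0))
    p <- 2 * stats::pt(t, df, lower.tail = FALSE)
    p[!is.finite(t)] <- 0
    pmax(p, .P_FLOOR)
}

#' Pearson correlation with a two-sided p-value
#'
#' Sample Pearson correlation over pairwise-complete positions (entries
#' missing in either vector are dropped), with the two-sided p-value
#' from \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}} on `n - 2` degrees of
#' freedom. Fewer than three complete pairs, or a zero-variance input,
#' makes the test unusable: the result is flagged rather than assigned
#' an arbitrary r.
#'
#' @param x,y Numeric vectors of equal length; `NA` marks missing.
#' @return List with `r`, `n_used`, `p`, and `usable` (`FALSE` when the
#'   correlation is undefined, in which case `r` and `p` are `NA`).
#' @export
#' @examples
#' pearsonWithP(c(1, 2, 3, 4, 5), c(1.2, 1.9, 3.4, 3.8, 5.1))
pearsonWithP <- function(x, y) {
    stopifnot(length(x) == length(y))
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
        return(list(r = NA_real_, n_used = n, p = NA_real_, usable = FALSE))
    r <- stats::cor(x[ok], y[ok])
    list(r = r, n_used = n, p = .pearsonP(r, n), usable = TRUE)
}

#' Spatially correlate every gene's expression map with one
#' imaging-diagnosis map
#'
#' For each gene, the expression values over the ROIs shared by the
#' expression matrix and the effect map are correlated (Pearson,
#' pairwise-complete) against the map's significance vector. The
#' default target is the unsigned `-log10(p)` map, matching how
#' significance maps are rendered; `target = "signed"` correlates
#' against `sign(beta) * -log10(p)` for direction-aware analyses.
#' Genes with fewer than three complete pairs or zero variance over the
#' common ROIs are excluded (count reported via `message()`), not
#' assigned r = 0, so they never enter the test family.
#'
#' @param expr A [RegionalExpression-class].
#' @param map An [EffectMap-class].
#' @param target `"neglog10p"` (default) or `"signed"`.
#' @return `DataFrame` with columns `gene`, `contrast`, `r`, `n_used`,
#'   `p`, one row per usable gene.
#' @export
correlateGenes <- function(expr, map, target = c("neglog10p", "signed")) {
    stopifnot(is(expr, "RegionalExpression"), is(map, "EffectMap"))
    target <- match.arg(target)
    common <- intersect(roiLabels(expr), roiLabels(map))
    if (length(common) < 3L)
        stop("expression matrix and effect map share ",
             length(common), " ROI(s); need at least 3")
    st <- map@stats
    yv <- st$neglog10p
    if (target == "signed") yv <- sign(st$beta) * yv
    names(yv) <- st$roi_label
    y <- yv[common]
    E <- exprMatrix(expr)[, common, drop = FALSE]

    # pairwise-complete moments via masked cross-products (y has no NAs)
    obs <- !is.na(E)
    E0 <- E
    E0[!obs] <- 0
    n <- rowSums(obs)
    sx <- rowSums(E0)
    sxx <- rowSums(E0^2)
    sy <- as.vector(obs %*% y)
    syy <- as.vector(obs %*% y^2)
    sxy <- as.vector(E0 %*% y)
    covxy <- sxy - sx * sy / n
    vx <- sxx - sx^2 / n
    vy <- syy - sy^2 / n
    usable <- n >= 3L & vx > 0 & vy > 0
    if (any(!usable))
        message(sum(!usable), " gene(s) unusable for ", map@contrast@name,
                ": < 3 complete pairs or zero variance; excluded")
    r <- rep(NA_real_, nrow(E))
    r[usable] <- covxy[usable] / sqrt(vx[usable] * vy[usable])
    r <- pmin(1, pmax(-1, r))
    DataFrame(gene = rownames(E)[usable],
              contrast = map@contrast@name,
              r = unname(r[usable]), n_used = unname(as.integer(n[usable])),
              p = unname(.pearsonP(r[usable], n[usable])))
}

#' Bonferroni adjustment over the pooled gene-by-contrast family
#'
#' Pools the per-contrast correlation results and adjusts every
#' p-value for the full family of tests actually performed:
#' `p_adjusted = min(1, p * familySize)`, significant iff
#' `p_adjusted < alpha`. With six contrasts, 10,027 usable genes and no
#' exclusions the family size is 60,162. The family size is reported
#' via `message()` because the correction is only valid for the family
#' actually tested.
#'
#' @param results A single `DataFrame` from [correlateGenes()] or a
#'   list of them (one per contrast).
#' @param alpha Family-wise significance level.
#' @param family `"pooled"` (default; all contrasts jointly) or
#'   `"per-contrast"` (each contrast's gene family separately).
#' @return A [CorrelationResults-class].
#' @export
bonferroniFamily <- function(results, alpha = 0.05,
                             family = c("pooled", "per-contrast")) {
    family <- match.arg(family)
    if (is(results, "DataFrame") || is.data.frame(results))
        results <- list(results)
    if (length(results) == 0L || sum(vapply(results, nrow, 0L)) == 0L)
        stop("no correlation results to adjust")
    if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
        stop("alpha must lie in (0, 1)")
    df <- do.call(rbind, lapply(results, DataFrame))
    if (family == "pooled") {
        df$p_adjusted <- pmin(1, df$p * nrow(df))
    } else {
        df$p_adjusted <- stats::ave(df$p, df$contrast,
                                    FUN = function(p) pmin(1, p * length(p)))
    }
    df$significant <- df$p_adjusted < alpha
    message("Bonferroni family size: ", nrow(df), " (", family,
            "), alpha = ", alpha)
    new("CorrelationResults", df, familySize = nrow(df), alpha = alpha)
}

#' Genes significant in every diagnostic contrast
#'
#' Intersects the adjusted results across all contrasts present: a gene
#' is retained only if its spatial correlation is family-wise
#' significant for every one of them.
#'
#' @param results A [CorrelationResults-class] (or compatible table
#'   with `gene`, `contrast`, `significant`).
#' @return Character vector of gene symbols, alphabetical.
#' @export
intersectAcrossContrasts <- function(results) {
    df <- as.data.frame(results)
    if (nrow(df) == 0L) return(character(0))
    contrasts <- unique(df$contrast)
    sig <- df[df$significant, , drop = FALSE]
    if (nrow(sig) == 0L) return(character(0))
    hits <- table(sig$gene)
    sort(names(hits)[hits == length(contrasts)], method = "radix")
}

#' Partition findings into known and novel genes
#'
#' Splits a gene list by membership in a disease-annotation set (the
#' DisGeNET role). Symbols are upper-cased on both sides before the
#' membership test.
#'
#' @param genes Character vector of gene symbols.
#' @param known Character vector, the annotation gene set (see
#'   [readGeneSet()]).
#' @return List with `known` and `novel`, both alphabetical.
#' @export
#' @examples
#' partitionByAnnotation(c("AQP9", "SPRN"), known = "AQP9")
partitionByAnnotation <- function(genes, known) {
    g <- toupper(genes)
    k <- toupper(known)
    list(known = sort(unique(g[g %in% k]), method = "radix"),
         novel = sort(unique(g[!g %in% k]), method = "radix"))
}
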