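#' @include AllClasses.R AllGenerics.R correlation.R
NULL

.writeMatrixCsv <- function(m, path, rowColName = "contrast",
                            fmt = .fmtNum) {
    body <- vapply(seq_len(nrow(m)), function(i)
        paste(c(rownames(m)[i], fmt(m[i, ])), collapse = ","), character(1))
    .writeLines(c(paste(c(rowColName, colnames(m)), collapse = ","), body),
                path)
    invisible(path)
}

#' Contrast-by-gene heat-map matrices of correlation results
#'
#' Builds the matrices behind the per-gene result heat maps: cells are
#' colored by `-log10(p)` of the spatial correlation, annotated with
#' the correlation coefficient rounded to two decimals, and marked
#' (`X`) where the family-adjusted test is significant. The matrices
#' are returned (and optionally written as CSV) so the rendering is
#' testable numerically; the optional PNG is a thin [pheatmap] layer
#' over the same numbers.
#'
#' @param results A [CorrelationResults-class].
#' @param genes Genes to display (columns); default all genes present.
#' @param csvPrefix If non-`NULL`, writes `<csvPrefix>_neglog10p.csv`,
#'   `<csvPrefix>_r.csv` and `<csvPrefix>_significant.csv`.
#' @param plotFile If non-`NULL`, renders a PNG heat map there.
#' @return List with matrices `neglog10p`, `r`, `significant`
#'   (contrast x gene) and `annotation` (r formatted to 2 decimals,
#'   with `" X"` appended where significant).
#' @export
correlationHeatmap <- function(results, genes = NULL, csvPrefix = NULL,
                               plotFile = NULL) {
    df <- as.data.frame(results)
    if (is.null(genes)) genes <- sort(unique(df$gene), method = "radix")
    if (length(genes) == 0L || nrow(df) == 0L)
        stop("no results to render")
    df <- df[df$gene %in% genes, , drop = FALSE]
    contrasts <- unique(df$contrast)
    shape <- function(v, default = NA_real_) {
        m <- matrix(default, length(contrasts), length(genes),
                    dimnames = list(contrasts, genes))
        m[cbind(match(df$contrast, contrasts), match(df$gene, genes))] <- v
        m
    }
    nlp <- shape(-log10(df$p))
    rm_ <- shape(df$r)
    sig <- shape(as.numeric(df$significant), default = 0) > 0
    ann <- matrix(paste0(formatC(rm_, format = "f", digits = 2),
                         ifelse(sig, " X", "")),
                  nrow(rm_), ncol(rm_), dimnames = dimnames(rm_))
    if (!is.null(csvPrefix)) {
        .writeMatrixCsv(nlp, paste0(csvPrefix, "_neglog10p.csv"))
        .writeMatrixCsv(rm_, paste0(csvPrefix, "_r.csv"))
        .writeMatrixCsv(sig + 0, paste0(csvPrefix, "_significant.csv"),
                        fmt = function(x) format(x, trim = TRUE))
    }
    if (!is.null(plotFile)) {
        grDevices::png(plotFile, width = 200 + 60 * ncol(nlp),
                       height = 150 + 40 * nrow(nlp), res = 110)
        on.exit(grDevices::dev.off())
        pheatmap::pheatmap(nlp, cluster_rows = FALSE, cluster_cols = FALSE,
                           display_numbers = ann,
                           main = "-log10(p) of gene-map spatial correlation")
    }
    list(neglog10p = nlp, r = rm_, significant = sig, annotation = ann)
}

#' Top-ROI summary table across contrasts
#'
#' For each imaging-diagnosis map, the `topK` most significant ROIs are
#' taken; the table reports the union of these ROIs (rows, sorted by
#' label) against the contrasts (columns), with a `-log10(p)` entry
#' only where the ROI is in that contrast's top `topK` and `NA`
#' (blank on disk) elsewhere — the sparse layout used for published
#' top-region tables.
#'
#' @param maps List of [EffectMap-class] objects.
#' @param topK Number of top ROIs per contrast (>= 1).
#' @param path Optional CSV output path.
#' @return `data.frame`, first column `roi_label`, then one `-log10(p)`
#'   column per contrast.
#' @export
roiSummaryTable <- function(maps, topK = 10, path = NULL) {
    if (length(maps) == 0L) stop("no effect maps supplied")
    if (!is.numeric(topK) || topK < 1) stop("topK must be >= 1")
    topK <- as.integer(topK)
    tops <- lapply(maps, function(m) {
        st <- m@stats
        ord <- order(-st$neglog10p, st$roi_label, method = "radix")
        st[utils::head(ord, topK), c("roi_label", "neglog10p")]
    })
    rois <- sort(unique(unlist(lapply(tops, function(t) t$roi_label))),
                 method = "radix")
    out <- data.frame(roi_label = rois)
    for (i in seq_along(maps)) {
        col <- rep(NA_real_, length(rois))
        col[match(tops[[i]]$roi_label, rois)] <- tops[[i]]$neglog10p
        out[[maps[[i]]@contrast@name]] <- col
    }
    if (!is.null(path)) {
        fmt <- function(x) ifelse(is.na(x), "", .fmtNum(x))
        body <- vapply(seq_len(nrow(out)), function(i)
            paste(c(out$roi_label[i],
                    fmt(as.numeric(out[i, -1L]))), collapse = ","),
            character(1))
        .writeLines(c(paste(colnames(out), collapse = ","), body), path)
    }
    out
}
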