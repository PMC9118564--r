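#' @include AllClasses.R AllGenerics.R
NULL

## All numeric output goes through %.17g: the shortest-ish decimal that
## round-trips IEEE doubles exactly, so write -> read -> write is
## byte-identical and loading never alters values.
.fmtNum <- function(x) sprintf("%.17g", x)

.readTable <- function(path, sep) {
    if (!file.exists(path)) stop("file not found: ", path)
    if (file.size(path) == 0L) stop("empty file: ", path)
    utils::read.table(path, header = TRUE, sep = sep, quote = "",
                      check.names = FALSE, colClasses = "character",
                      na.strings = c("", "NA"), comment.char = "")
}

.writeLines <- function(lines, path) {
    con <- file(path, open = "wb")   # \n endings on every platform
    on.exit(close(con))
    writeLines(lines, con, sep = "\n")
}

# ---------------------------------------------------------------------------
# Phenotypes
# ---------------------------------------------------------------------------

#' Read a subject phenotype table
#'
#' Reads a CSV with header columns `subject_id`, `diagnosis`, `age`,
#' `sex`, `education`. Rows with missing or unparseable covariates are
#' dropped (the count is reported via `message()`); no imputation is
#' attempted. A diagnosis label outside CN/EMCI/LMCI/AD is a hard error
#' naming the offending row, as is a duplicated subject id or an empty
#' file.
#'
#' @param path Path to the phenotype CSV.
#' @return `data.frame` with columns `subject_id` (character),
#'   `diagnosis` (factor over [diagnosisLevels()]), `age`, `sex`,
#'   `education` (numeric). Sex is coded 1 = male, 0 = female.
#' @export
readPhenotypes <- function(path) {
    raw <- .readTable(path, sep = ",")
    needed <- c("subject_id", "diagnosis", "age", "sex", "education")
    miss <- setdiff(needed, colnames(raw))
    if (length(miss))
        stop("phenotype file lacks column(s): ", paste(miss, collapse = ", "))
    if (nrow(raw) == 0L) stop("phenotype file has no data rows: ", path)

    bad.dx <- which(!is.na(raw$diagnosis) &
                    !raw$diagnosis %in% .DIAGNOSIS_LEVELS)
    if (length(bad.dx))
        stop(sprintf("unknown diagnosis label \"%s\" in row %d of %s",
                     raw$diagnosis[bad.dx[1L]], bad.dx[1L], path))

    num <- function(v) suppressWarnings(as.numeric(v))
    ph <- data.frame(subject_id = raw$subject_id,
                     diagnosis = raw$diagnosis,
                     age = num(raw$age), sex = num(raw$sex),
                     education = num(raw$education))
    keep <- stats::complete.cases(ph)
    if (any(!keep))
        message(sum(!keep), " row(s) with missing/unparseable fields dropped")
    ph <- ph[keep, , drop = FALSE]
    if (nrow(ph) == 0L) stop("no usable phenotype rows in ", path)
    if (anyDuplicated(ph$subject_id))
        stop("duplicated subject_id in ", path, ": ",
             ph$subject_id[duplicated(ph$subject_id)][1L])
    ph$diagnosis <- factor(ph$diagnosis, levels = .DIAGNOSIS_LEVELS)
    rownames(ph) <- NULL
    ph
}

#' Write a phenotype table
#'
#' Inverse of [readPhenotypes()]; numeric columns are written at full
#' double precision so the pair round-trips exactly.
#'
#' @param phenotypes `data.frame` as returned by [readPhenotypes()], or
#'   an [ImagingCohort-class] whose `colData` is exported.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writePhenotypes <- function(phenotypes, path) {
    if (is(phenotypes, "ImagingCohort")) {
        cd <- colData(phenotypes)
        phenotypes <- data.frame(subject_id = rownames(cd),
                                 diagnosis = as.character(cd$diagnosis),
                                 age = cd$age, sex = cd$sex,
                                 education = cd$education)
    }
    lines <- c("subject_id,diagnosis,age,sex,education",
               paste(phenotypes$subject_id, as.character(phenotypes$diagnosis),
                     .fmtNum(phenotypes$age), .fmtNum(phenotypes$sex),
                     .fmtNum(phenotypes$education), sep = ","))
    .writeLines(lines, path)
    invisible(path)
}

# ---------------------------------------------------------------------------
# Imaging matrix / cohort
# ---------------------------------------------------------------------------

#' Read an imaging cohort from phenotype and imaging CSVs
#'
#' The imaging CSV holds one row per subject: a `subject_id` column
#' followed by one column per atlas ROI (HCPMMP-style labels such as
#' `L_7m_ROI`). Subjects are aligned to the phenotype table by id;
#' subjects present in the phenotypes but absent from the imaging file
#' are a hard error, and non-finite trait values are rejected.
#'
#' @param phenotypePath Path to the phenotype CSV (see [readPhenotypes()]).
#' @param imagingPath Path to the subjects x ROIs imaging CSV.
#' @return An [ImagingCohort-class].
#' @export
readImagingCohort <- function(phenotypePath, imagingPath) {
    ph <- readPhenotypes(phenotypePath)
    raw <- .readTable(imagingPath, sep = ",")
    if (colnames(raw)[1L] != "subject_id")
        stop("imaging file must start with a subject_id column")
    if (ncol(raw) < 2L) stop("imaging file has no ROI columns")
    ids <- raw$subject_id
    if (anyDuplicated(ids)) stop("duplicated subject_id in ", imagingPath)
    miss <- setdiff(ph$subject_id, ids)
    if (length(miss))
        stop("subject(s) missing from imaging file: ",
             paste(utils::head(miss, 5L), collapse = ", "))
    m <- as.matrix(raw[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    ImagingCohort(m[ph$subject_id, , drop = FALSE], ph)
}

#' Write the imaging matrix of a cohort
#'
#' Writes a subjects x ROIs CSV (`subject_id` first column) at full
#' double precision; the [readImagingCohort()] / [writeImaging()] pair
#' round-trips exactly.
#'
#' @param cohort An [ImagingCohort-class].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeImaging <- function(cohort, path) {
    m <- t(traitMatrix(cohort))   # subjects x ROIs on disk
    body <- vapply(seq_len(nrow(m)), function(i)
        paste(c(rownames(m)[i], .fmtNum(m[i, ])), collapse = ","),
        character(1))
    .writeLines(c(paste(c("subject_id", colnames(m)), collapse = ","), body),
                path)
    invisible(path)
}

# ---------------------------------------------------------------------------
# Expression
# ---------------------------------------------------------------------------

#' Read a regional expression matrix
#'
#' Reads a TSV whose first column is the gene symbol and whose remaining
#' columns are ROI labels; empty cells are missing values. Genes with
#' fewer than three non-missing ROI values cannot support a spatial
#' correlation and are excluded at load (count reported via
#' `message()`). A duplicated gene symbol or a file without ROI columns
#' is a hard error.
#'
#' @param path Path to the genes x ROIs TSV.
#' @return A [RegionalExpression-class].
#' @export
readExpression <- function(path) {
    raw <- .readTable(path, sep = "\t")
    if (ncol(raw) < 2L) stop("expression file has no ROI columns: ", path)
    genes <- raw[[1L]]
    if (anyDuplicated(genes))
        stop("duplicated gene symbol in ", path, ": ",
             genes[duplicated(genes)][1L])
    m <- as.matrix(raw[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- genes
    keep <- rowSums(!is.na(m)) >= 3L
    if (any(!keep))
        message(sum(!keep),
                " gene(s) with < 3 non-missing ROI values excluded")
    if (!any(keep)) stop("no usable genes in ", path)
    RegionalExpression(m[keep, , drop = FALSE])
}

#' Write a regional expression matrix
#'
#' Inverse of [readExpression()]: genes x ROIs TSV, missing values as
#' empty cells, full double precision.
#'
#' @param expr A [RegionalExpression-class].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(expr, path) {
    m <- exprMatrix(expr)
    fm <- matrix(.fmtNum(m), nrow(m), ncol(m))
    fm[is.na(m)] <- ""
    body <- vapply(seq_len(nrow(m)), function(i)
        paste(c(rownames(m)[i], fm[i, ]), collapse = "\t"), character(1))
    .writeLines(c(paste(c("gene", colnames(m)), collapse = "\t"), body), path)
    invisible(path)
}

# ---------------------------------------------------------------------------
# Gene sets
# ---------------------------------------------------------------------------

#' Read a disease-gene annotation list
#'
#' One gene symbol per line. Symbols are upper-cased before any
#' membership test because annotation databases and expression atlases
#' capitalize inconsistently; duplicates collapse. An empty file yields
#' an empty set with a warning (the pipeline still runs; every finding
#' is then "novel").
#'
#' @param path Path to the gene list.
#' @return Character vector of unique upper-case symbols.
#' @export
readGeneSet <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    x <- trimws(readLines(path, warn = FALSE))
    x <- unique(toupper(x[nzchar(x)]))
    if (length(x) == 0L)
        warning("gene-set file is empty: ", path,
                " - all findings will be reported as novel")
    x
}

# ---------------------------------------------------------------------------
# Result tables
# ---------------------------------------------------------------------------

#' Write gene-map correlation results
#'
#' Fixed column order `gene, contrast, r, n_used, p, p_adjusted,
#' significant`; numerics at full double precision so a written table
#' reloads and re-writes byte-identically.
#'
#' @param results A [CorrelationResults-class] or any table with the
#'   columns above.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeCorrelationResults <- function(results, path) {
    df <- as.data.frame(results)
    lines <- c("gene,contrast,r,n_used,p,p_adjusted,significant",
               paste(df$gene, df$contrast, .fmtNum(df$r),
                     format(df$n_used, scientific = FALSE, trim = TRUE),
                     .fmtNum(df$p), .fmtNum(df$p_adjusted),
                     ifelse(df$significant, "TRUE", "FALSE"), sep = ","))
    .writeLines(lines, path)
    invisible(path)
}

#' Read gene-map correlation results
#'
#' Inverse of [writeCorrelationResults()].
#'
#' @param path Path to a results CSV.
#' @return `DataFrame` with the fixed result columns.
#' @export
readCorrelationResults <- function(path) {
    raw <- .readTable(path, sep = ",")
    needed <- c("gene", "contrast", "r", "n_used", "p", "p_adjusted",
                "significant")
    miss <- setdiff(needed, colnames(raw))
    if (length(miss))
        stop("results file lacks column(s): ", paste(miss, collapse = ", "))
    DataFrame(gene = raw$gene, contrast = raw$contrast,
              r = as.numeric(raw$r), n_used = as.integer(raw$n_used),
              p = as.numeric(raw$p), p_adjusted = as.numeric(raw$p_adjusted),
              significant = raw$significant == "TRUE")
}

#' Write / read an imaging-diagnosis map
#'
#' Effect maps are written one CSV per contrast with columns
#' `roi_label, beta, se, t, p, neglog10p` plus a `contrast` column so
#' the file is self-describing.
#'
#' @param map An [EffectMap-class].
#' @param path CSV path.
#' @return `writeEffectMap`: `path`, invisibly. `readEffectMap`: an
#'   [EffectMap-class].
#' @export
writeEffectMap <- function(map, path) {
    st <- map@stats
    lines <- c("roi_label,contrast,beta,se,t,p,neglog10p",
               paste(st$roi_label, map@contrast@name, .fmtNum(st$beta),
                     .fmtNum(st$se), .fmtNum(st$t), .fmtNum(st$p),
                     .fmtNum(st$neglog10p), sep = ","))
    .writeLines(lines, path)
    invisible(path)
}

#' @rdname writeEffectMap
#' @param nSubjects Subject count to record on the reloaded map (the
#'   CSV itself does not carry it); defaults to `NA`.
#' @export
readEffectMap <- function(path, nSubjects = NA_integer_) {
    raw <- .readTable(path, sep = ",")
    cn <- unique(raw$contrast)
    if (length(cn) != 1L)
        stop("effect-map file must describe exactly one contrast: ", path)
    new("EffectMap", contrast = parseContrastName(cn),
        stats = DataFrame(roi_label = raw$roi_label,
                          beta = as.numeric(raw$beta),
                          se = as.numeric(raw$se),
                          t = as.numeric(raw$t),
                          p = as.numeric(raw$p),
                          neglog10p = as.numeric(raw$neglog10p)),
        nSubjects = as.integer(nSubjects))
}

#' Parse a contrast name back into a DiagnosisContrast
#'
#' @param name Name of the form `"CN_vs_EMCI+LMCI"`.
#' @return A [DiagnosisContrast-class].
#' @export
parseContrastName <- function(name) {
    parts <- strsplit(name, "_vs_", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) stop("malformed contrast name: ", name)
    DiagnosisContrast(strsplit(parts[2L], "+", fixed = TRUE)[[1L]],
                      control = parts[1L])
}

# ---------------------------------------------------------------------------
# Hemisphere filtering
# ---------------------------------------------------------------------------

#' Restrict atlas labels to one hemisphere
#'
#' HCPMMP-style labels carry a hemisphere prefix (`L_` or `R_`); beyond
#' that prefix the label is opaque. The transcriptome atlas samples the
#' left hemisphere far more densely, so analyses are typically run on
#' the 180 left parcels out of the full 360.
#'
#' @param labels Character vector of ROI labels.
#' @param prefix Hemisphere prefix to keep, `"L_"` (default) or `"R_"`.
#' @return The labels matching `prefix`, original order preserved.
#'   Labels without a recognized hemisphere prefix are a hard error
#'   listing the offenders.
#' @export
#' @examples
#' filterHemisphere(c("L_7m_ROI", "R_7m_ROI", "L_V1_ROI"))
filterHemisphere <- function(labels, prefix = "L_") {
    prefix <- match.arg(prefix, c("L_", "R_"))
    bad <- !(startsWith(labels, "L_") | startsWith(labels, "R_"))
    if (any(bad))
        stop("label(s) without L_/R_ hemisphere prefix: ",
             paste(utils::head(labels[bad], 5L), collapse = ", "))
    labels[startsWith(labels, prefix)]
}
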