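#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importClassesFrom S4Vectors DFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

## Ordered clinical stages. CN is always the control; the three case stages
## are ordered by disease progression (EMCI < LMCI < AD).
.DIAGNOSIS_LEVELS <- c("CN", "EMCI", "LMCI", "AD")
.CASE_STAGES <- c("EMCI", "LMCI", "AD")

#' Diagnosis levels used throughout the package
#'
#' The four-level clinical staging used by the pipeline, in progression
#' order: cognitively normal (CN), early and late mild cognitive
#' impairment (EMCI, LMCI), and Alzheimer's disease (AD).
#'
#' @return Character vector of the four stage labels.
#' @export
#' @examples
#' diagnosisLevels()
diagnosisLevels <- function() .DIAGNOSIS_LEVELS

# ---------------------------------------------------------------------------
# DiagnosisContrast
# ---------------------------------------------------------------------------

#' Case-control diagnostic contrast
#'
#' A contrast pairs the CN control group with a pooled, stage-contiguous
#' set of case groups (e.g. `CN vs LMCI+AD`). Contiguity in the
#' progression order EMCI < LMCI < AD is enforced: a contrast pooling
#' EMCI with AD while skipping LMCI is invalid because the pooled cases
#' would not represent a coherent disease-severity interval.
#'
#' @slot name Character, deterministic name `"CN_vs_<stage>+<stage>..."`.
#' @slot control Character, always `"CN"`.
#' @slot cases Character vector, non-empty contiguous subset of
#'   `c("EMCI", "LMCI", "AD")` in progression order.
#'
#' @seealso [buildContrasts()]
#' @export
setClass("DiagnosisContrast",
    representation(name = "character", control = "character",
                   cases = "character"))

setValidity("DiagnosisContrast", function(object) {
    msg <- NULL
    if (length(object@control) != 1L || object@control != "CN")
        msg <- c(msg, "control must be \"CN\"")
    if (length(object@cases) == 0L)
        msg <- c(msg, "cases must be non-empty")
    if (!all(object@cases %in% .CASE_STAGES))
        msg <- c(msg, sprintf("unknown case stage(s): %s",
                 paste(setdiff(object@cases, .CASE_STAGES), collapse = ", ")))
    idx <- match(object@cases, .CASE_STAGES)
    if (!anyNA(idx)) {
        if (is.unsorted(idx, strictly = TRUE))
            msg <- c(msg, "cases must be in progression order EMCI < LMCI < AD")
        if (length(idx) > 1L && any(diff(idx) != 1L))
            msg <- c(msg, sprintf(
                "cases {%s} are not contiguous in the progression order",
                paste(object@cases, collapse = ", ")))
    }
    if (object@control %in% object@cases)
        msg <- c(msg, "control cannot also be a case")
    if (is.null(msg)) TRUE else msg
})

#' Construct a diagnostic contrast
#'
#' @param cases Character vector of case stages, a contiguous run of
#'   `c("EMCI", "LMCI", "AD")`.
#' @param control Control group label; only `"CN"` is supported.
#' @return A [DiagnosisContrast-class] object.
#' @export
#' @examples
#' DiagnosisContrast(c("LMCI", "AD"))
DiagnosisContrast <- function(cases, control = "CN") {
    cases <- as.character(cases)
    new("DiagnosisContrast",
        name = paste0(control, "_vs_", paste(cases, collapse = "+")),
        control = control, cases = cases)
}

setMethod("show", "DiagnosisContrast", function(object) {
    cat("DiagnosisContrast:", object@name, "\n")
})

# ---------------------------------------------------------------------------
# ImagingCohort
# ---------------------------------------------------------------------------

#' Imaging cohort: regional trait values with subject phenotypes
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' whose single assay `"trait"` holds ROI x subject imaging-trait values
#' (e.g. AV45 amyloid SUVR per HCPMMP parcel) and whose `colData` carries
#' the per-subject phenotype: `diagnosis` (factor over CN/EMCI/LMCI/AD),
#' `age` (years), `sex` (1 = male, 0 = female) and `education` (years).
#'
#' Validity requires unique subject identifiers and ROI labels, finite
#' trait values, complete covariates, and diagnosis labels drawn only
#' from the four-level staging.
#'
#' @seealso [ImagingCohort()], [readImagingCohort()], [generateCohort()]
#' @export
setClass("ImagingCohort", contains = "SummarizedExperiment")

setValidity("ImagingCohort", function(object) {
    msg <- NULL
    if (!"trait" %in% SummarizedExperiment::assayNames(object))
        return("assay \"trait\" is required")
    cd <- colData(object)
    needed <- c("diagnosis", "age", "sex", "education")
    miss <- setdiff(needed, colnames(cd))
    if (length(miss))
        return(sprintf("colData lacks column(s): %s", paste(miss, collapse = ", ")))
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "subject ids must be unique")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "ROI labels must be unique")
    dx <- as.character(cd$diagnosis)
    if (!all(dx %in% .DIAGNOSIS_LEVELS))
        msg <- c(msg, sprintf("unknown diagnosis label(s): %s",
                 paste(unique(setdiff(dx, .DIAGNOSIS_LEVELS)), collapse = ", ")))
    cov <- cbind(cd$age, cd$sex, cd$education)
    if (any(!is.finite(cov)))
        msg <- c(msg, "covariates must be complete and finite")
    if (any(cd$age <= 0)) msg <- c(msg, "age must be positive")
    if (any(cd$education < 0)) msg <- c(msg, "education must be non-negative")
    if (!all(cd$sex %in% c(0, 1))) msg <- c(msg, "sex must be coded 0/1")
    if (any(!is.finite(assay(object, "trait"))))
        msg <- c(msg, "trait values must be finite")
    if (is.null(msg)) TRUE else msg
})

#' Construct an imaging cohort
#'
#' @param trait Numeric matrix, subjects x ROIs (rows are subjects, as in
#'   the on-disk CSV layout) or ROIs x subjects; orientation is resolved
#'   against `phenotypes$subject_id`.
#' @param phenotypes `data.frame` with columns `subject_id`, `diagnosis`,
#'   `age`, `sex`, `education`, one row per subject.
#' @return An [ImagingCohort-class] object (ROIs x subjects internally).
#' @export
#' @examples
#' ph <- data.frame(subject_id = c("s1", "s2"),
#'                  diagnosis = c("CN", "AD"), age = c(70, 75),
#'                  sex = c(1, 0), education = c(16, 12))
#' tr <- matrix(rnorm(4), 2, 2,
#'              dimnames = list(c("s1", "s2"), c("L_A_ROI", "L_B_ROI")))
#' ImagingCohort(tr, ph)
ImagingCohort <- function(trait, phenotypes) {
    stopifnot(is.matrix(trait), is.data.frame(phenotypes))
    ids <- as.character(phenotypes$subject_id)
    if (!is.null(rownames(trait)) && all(ids %in% rownames(trait)))
        trait <- t(trait[ids, , drop = FALSE])   # subjects x ROIs on disk
    else if (!is.null(colnames(trait)) && all(ids %in% colnames(trait)))
        trait <- trait[, ids, drop = FALSE]
    else
        stop("trait matrix dimnames do not cover the phenotype subject_ids")
    cd <- DataFrame(
        diagnosis = factor(as.character(phenotypes$diagnosis),
                           levels = .DIAGNOSIS_LEVELS),
        age = as.numeric(phenotypes$age),
        sex = as.numeric(phenotypes$sex),
        education = as.numeric(phenotypes$education),
        row.names = ids)
    new("ImagingCohort", SummarizedExperiment(
        assays = list(trait = trait), colData = cd))
}

setMethod("show", "ImagingCohort", function(object) {
    cat(class(object), "with", ncol(object), "subjects x", nrow(object),
        "ROIs\n")
    print(table(diagnosis(object)))
})

# ---------------------------------------------------------------------------
# RegionalExpression
# ---------------------------------------------------------------------------

#' Regional gene expression maps
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' whose single assay `"expr"` holds genes x ROIs normalized expression
#' (AHBA-style, unitless). Missing values are permitted per (gene, ROI);
#' validity requires unique gene symbols and ROI labels and at least
#' three non-missing ROI values per gene (sparser genes are dropped at
#' read time by [readExpression()]).
#'
#' @seealso [readExpression()], [generateExpression()]
#' @export
setClass("RegionalExpression", contains = "SummarizedExperiment")

setValidity("RegionalExpression", function(object) {
    msg <- NULL
    if (!"expr" %in% SummarizedExperiment::assayNames(object))
        return("assay \"expr\" is required")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "gene symbols must be unique")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "ROI labels must be unique")
    nu <- rowSums(!is.na(assay(object, "expr")))
    if (any(nu < 3L))
        msg <- c(msg, sprintf(
            "%d gene(s) have < 3 non-missing ROI values; drop them first",
            sum(nu < 3L)))
    if (is.null(msg)) TRUE else msg
})

#' Construct a regional expression object
#'
#' @param expr Numeric matrix, genes x ROIs, with gene symbols as
#'   rownames and ROI labels as colnames; `NA` marks missing values.
#' @return A [RegionalExpression-class] object.
#' @export
RegionalExpression <- function(expr) {
    stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
    new("RegionalExpression",
        SummarizedExperiment(assays = list(expr = expr)))
}

setMethod("show", "RegionalExpression", function(object) {
    cat(class(object), "with", nrow(object), "genes x", ncol(object),
        "ROIs;", sum(is.na(assay(object, "expr"))), "missing entries\n")
})

# ---------------------------------------------------------------------------
# EffectMap
# ---------------------------------------------------------------------------

#' Imaging-diagnosis significance map
#'
#' Per-ROI diagnostic-effect statistics for one case-control contrast:
#' the diagnosis coefficient (`beta`, trait units), its standard error,
#' t statistic, two-sided p-value, and `neglog10p = -log10(p)` (the
#' rendering used for significance maps; p is floored at 1e-300 first).
#' Records are sorted by ROI label.
#'
#' @slot contrast The [DiagnosisContrast-class] the map belongs to.
#' @slot stats `DFrame` with columns `roi_label`, `beta`, `se`, `t`,
#'   `p`, `neglog10p`, one row per analyzed ROI.
#' @slot nSubjects Integer, subjects used in the per-ROI regressions.
#'
#' @seealso [effectMap()], [significantRois()]
#' @export
setClass("EffectMap",
    representation(contrast = "DiagnosisContrast", stats = "DFrame",
                   nSubjects = "integer"))

setValidity("EffectMap", function(object) {
    msg <- NULL
    st <- object@stats
    needed <- c("roi_label", "beta", "se", "t", "p", "neglog10p")
    miss <- setdiff(needed, colnames(st))
    if (length(miss))
        return(sprintf("stats lacks column(s): %s", paste(miss, collapse = ", ")))
    if (anyDuplicated(st$roi_label)) msg <- c(msg, "duplicate ROI labels")
    if (any(st$p <= 0 | st$p > 1)) msg <- c(msg, "p must lie in (0, 1]")
    if (any(st$neglog10p < 0)) msg <- c(msg, "neglog10p must be >= 0")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "EffectMap", function(object) {
    cat("EffectMap for", object@contrast@name, "-", nrow(object@stats),
        "ROIs,", object@nSubjects, "subjects\n")
    cat("  max -log10(p):", round(max(object@stats$neglog10p), 2), "at",
        object@stats$roi_label[which.max(object@stats$neglog10p)], "\n")
})

#' @describeIn EffectMap-class coerce the per-ROI statistics to a
#'   base `data.frame`.
#' @param x,row.names,optional,... see [base::as.data.frame()].
#' @export
setMethod("as.data.frame", "EffectMap",
    function(x, row.names = NULL, optional = FALSE, ...) {
        as.data.frame(x@stats, row.names = row.names, optional = optional, ...)
    })

# ---------------------------------------------------------------------------
# CorrelationResults
# ---------------------------------------------------------------------------

#' Family-adjusted gene-map correlation results
#'
#' A `DFrame` of per (gene, contrast) spatial-correlation tests with
#' columns `gene`, `contrast`, `r`, `n_used`, `p`, `p_adjusted`,
#' `significant`, carrying the Bonferroni family size and alpha used for
#' adjustment as slots. `p_adjusted = min(1, p * familySize)` and
#' `significant <=> p_adjusted < alpha`.
#'
#' @slot familySize Integer, number of usable tests in the family.
#' @slot alpha Numeric, family-wise significance level.
#'
#' @seealso [bonferroniFamily()], [correlateGenes()]
#' @export
setClass("CorrelationResults", contains = "DFrame",
    representation(familySize = "integer", alpha = "numeric"))

setMethod("show", "CorrelationResults", function(object) {
    cat("CorrelationResults:", nrow(object), "tests, family size",
        object@familySize, ", alpha", object@alpha, "-",
        sum(object$significant), "significant\n")
})

# ---------------------------------------------------------------------------
# Synthetic data: config and ground truth
# ---------------------------------------------------------------------------

#' Configuration of the synthetic cohort generator
#'
#' Collects every parameter of the synthetic phenotype / imaging /
#' expression generator; see [syntheticConfig()] for field semantics
#' and defaults.
#'
#' @seealso [syntheticConfig()], [generateCohort()], [generateExpression()]
#' @export
setClass("SyntheticConfig",
    representation(
        groupSizes = "integer",        # named CN/EMCI/LMCI/AD
        nRois = "integer",
        roiLabels = "character",
        affectedRoiFraction = "numeric",
        effectSizes = "numeric",       # named EMCI/LMCI/AD, trait units
        covariateEffects = "numeric",  # named age/sex/education slopes
        noiseSd = "numeric",
        baselineMean = "numeric",
        baselineSd = "numeric",
        ageMean = "numeric",           # per group
        ageSd = "numeric",
        maleFraction = "numeric",      # per group
        educationMean = "numeric",     # per group
        educationSd = "numeric",
        nGenes = "integer",
        nSignalGenes = "integer",
        signalRTarget = "numeric",
        expressionMissingRate = "numeric",
        nKnownSignalGenes = "integer",
        nKnownGenes = "integer",
        seed = "integer"))

setValidity("SyntheticConfig", function(object) {
    msg <- NULL
    if (!identical(names(object@groupSizes), .DIAGNOSIS_LEVELS))
        msg <- c(msg, "groupSizes must be named CN, EMCI, LMCI, AD")
    if (any(object@groupSizes <= 0L)) msg <- c(msg, "group sizes must be positive")
    if (object@nRois <= 0L) msg <- c(msg, "nRois must be positive")
    if (length(object@roiLabels) &&
        length(object@roiLabels) != object@nRois)
        msg <- c(msg, "roiLabels length must equal nRois")
    if (object@affectedRoiFraction < 0 || object@affectedRoiFraction > 1)
        msg <- c(msg, "affectedRoiFraction must lie in [0, 1]")
    if (!identical(names(object@effectSizes), .CASE_STAGES))
        msg <- c(msg, "effectSizes must be named EMCI, LMCI, AD")
    if (is.unsorted(object@effectSizes))
        msg <- c(msg, "effectSizes must be monotone non-decreasing over EMCI -> LMCI -> AD")
    if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be positive")
    if (object@nSignalGenes > object@nGenes)
        msg <- c(msg, "nSignalGenes cannot exceed nGenes")
    if (object@nSignalGenes > 0 &&
        (object@signalRTarget <= 0 || object@signalRTarget >= 1))
        msg <- c(msg, "signalRTarget must lie in (0, 1)")
    if (object@expressionMissingRate < 0 || object@expressionMissingRate >= 1)
        msg <- c(msg, "expressionMissingRate must lie in [0, 1)")
    if (object@nKnownSignalGenes > object@nSignalGenes)
        msg <- c(msg, "nKnownSignalGenes cannot exceed nSignalGenes")
    if (is.null(msg)) TRUE else msg
})

#' Ground truth of a synthetic study
#'
#' Records what the generator planted, so downstream recovery can be
#' scored: the affected ROI labels, the noiseless per-ROI effect profile
#' (unit-free shape; stage effects scale it into trait units), the
#' planted signal genes with their realized spatial correlations to the
#' true profile, the synthetic disease-annotation gene set, and the seed.
#'
#' @export
setClass("GroundTruth",
    representation(
        affectedRois = "character",
        effectProfile = "numeric",     # named by ROI label, unit-free shape
        signalGenes = "character",
        realizedR = "numeric",         # named by signal gene
        knownGenes = "character",      # synthetic annotation list
        seed = "integer"))

setMethod("show", "GroundTruth", function(object) {
    cat("GroundTruth:", length(object@affectedRois), "affected ROIs,",
        length(object@signalGenes), "signal genes, seed", object@seed, "\n")
})
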