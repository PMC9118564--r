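#' @include AllClasses.R
NULL

#' Accessors for BrainTxMap containers
#'
#' Small accessor generics shared by the package's S4 classes:
#' `roiLabels()` returns atlas ROI labels, `subjectIds()` the subject
#' identifiers of a cohort, `geneSymbols()` the gene symbols of an
#' expression object, `diagnosis()` the per-subject diagnosis factor,
#' `traitMatrix()` / `exprMatrix()` the underlying assay matrices, and
#' `contrastName()` the deterministic name of a contrast or effect map.
#'
#' @param x A package object (see Methods).
#' @return A character vector, factor or matrix as appropriate.
#' @name accessors
#' @aliases roiLabels subjectIds geneSymbols diagnosis traitMatrix
#'   exprMatrix contrastName
#' @examples
#' cfg <- syntheticConfig(groupSizes = c(CN = 5, EMCI = 5, LMCI = 5, AD = 5),
#'                        nRois = 8, nGenes = 10, nSignalGenes = 2, seed = 1)
#' cohort <- generateCohort(cfg)$cohort
#' head(roiLabels(cohort))
#' table(diagnosis(cohort))
NULL

#' @rdname accessors
#' @export
setGeneric("roiLabels", function(x) standardGeneric("roiLabels"))

#' @rdname accessors
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname accessors
#' @export
setGeneric("geneSymbols", function(x) standardGeneric("geneSymbols"))

#' @rdname accessors
#' @export
setGeneric("diagnosis", function(x) standardGeneric("diagnosis"))

#' @rdname accessors
#' @export
setGeneric("traitMatrix", function(x) standardGeneric("traitMatrix"))

#' @rdname accessors
#' @export
setGeneric("exprMatrix", function(x) standardGeneric("exprMatrix"))

#' @rdname accessors
#' @export
setGeneric("contrastName", function(x) standardGeneric("contrastName"))

#' @rdname accessors
setMethod("roiLabels", "ImagingCohort", function(x) rownames(x))

#' @rdname accessors
setMethod("roiLabels", "RegionalExpression", function(x) colnames(x))

#' @rdname accessors
setMethod("roiLabels", "EffectMap", function(x) x@stats$roi_label)

#' @rdname accessors
setMethod("subjectIds", "ImagingCohort", function(x) colnames(x))

#' @rdname accessors
setMethod("geneSymbols", "RegionalExpression", function(x) rownames(x))

#' @rdname accessors
setMethod("diagnosis", "ImagingCohort",
    function(x) colData(x)$diagnosis)

#' @rdname accessors
setMethod("traitMatrix", "ImagingCohort",
    function(x) assay(x, "trait"))

#' @rdname accessors
setMethod("exprMatrix", "RegionalExpression",
    function(x) assay(x, "expr"))

#' @rdname accessors
setMethod("contrastName", "DiagnosisContrast", function(x) x@name)

#' @rdname accessors
setMethod("contrastName", "EffectMap", function(x) x@contrast@name)
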