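## Accessor generics shared across the package's classes.

#' Accessors for dvhqa objects
#'
#' Small accessor family: plan ids, dose axis, OAR label, clinical/predicted
#' volume matrices, the per-plan scalar feature, error-summary components, and
#' band/coverage components. Bioconductor-style: use these rather than `@`.
#'
#' @param x a [DVHCohort], [ErrorSummary], [PredictionBand] or
#'   [CoverageCurve] as appropriate.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("planIds", function(x) standardGeneric("planIds"))

#' @rdname accessors
#' @export
setGeneric("doseValues", function(x) standardGeneric("doseValues"))

#' @rdname accessors
#' @export
setGeneric("nPlans", function(x) standardGeneric("nPlans"))

#' @rdname accessors
#' @export
setGeneric("oarLabel", function(x) standardGeneric("oarLabel"))

#' @rdname accessors
#' @export
setGeneric("clinicalVolumes", function(x) standardGeneric("clinicalVolumes"))

#' @rdname accessors
#' @export
setGeneric("predictedVolumes", function(x) standardGeneric("predictedVolumes"))

#' @rdname accessors
#' @export
setGeneric("planFeature", function(x) standardGeneric("planFeature"))

#' @rdname accessors
#' @export
setGeneric("errorBias", function(x) standardGeneric("errorBias"))

#' @rdname accessors
#' @export
setGeneric("errorSD", function(x) standardGeneric("errorSD"))

#' @rdname accessors
#' @export
setGeneric("errorSDPop", function(x) standardGeneric("errorSDPop"))

#' @rdname accessors
#' @export
setGeneric("errorRMSE", function(x) standardGeneric("errorRMSE"))

#' @rdname accessors
#' @export
setGeneric("bandKind", function(x) standardGeneric("bandKind"))

#' @rdname accessors
#' @export
setGeneric("bandLower", function(x) standardGeneric("bandLower"))

#' @rdname accessors
#' @export
setGeneric("bandUpper", function(x) standardGeneric("bandUpper"))

#' @rdname accessors
#' @export
setGeneric("bandScope", function(x) standardGeneric("bandScope"))

#' @rdname accessors
#' @export
setGeneric("rawCoverage", function(x) standardGeneric("rawCoverage"))

#' @rdname accessors
#' @export
setGeneric("smoothedCoverage", function(x) standardGeneric("smoothedCoverage"))

## --- DVHCohort -------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("planIds", "DVHCohort", function(x) colnames(x))

#' @rdname accessors
#' @export
setMethod("doseValues", "DVHCohort", function(x) rowData(x)$dose_pct)

#' @rdname accessors
#' @export
setMethod("nPlans", "DVHCohort", function(x) ncol(x))

#' @rdname accessors
#' @export
setMethod("oarLabel", "DVHCohort", function(x) metadata(x)$oar)

#' @rdname accessors
#' @export
setMethod("clinicalVolumes", "DVHCohort", function(x) assay(x, "clinical"))

#' @rdname accessors
#' @export
setMethod("predictedVolumes", "DVHCohort", function(x) assay(x, "predicted"))

#' @rdname accessors
#' @export
setMethod("planFeature", "DVHCohort", function(x) {
  f <- colData(x)$feature
  if (is.null(f)) return(NULL)
  stats::setNames(f, colnames(x))
})

## --- ErrorSummary ----------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("doseValues", "ErrorSummary", function(x) x@dose)

#' @rdname accessors
#' @export
setMethod("nPlans", "ErrorSummary", function(x) x@n)

#' @rdname accessors
#' @export
setMethod("errorBias", "ErrorSummary", function(x) x@mu)

#' @rdname accessors
#' @export
setMethod("errorSD", "ErrorSummary", function(x) x@sigma)

#' @rdname accessors
#' @export
setMethod("errorSDPop", "ErrorSummary", function(x) x@sigmaPop)

#' @rdname accessors
#' @export
setMethod("errorRMSE", "ErrorSummary", function(x) x@rmse)

## --- PredictionBand --------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("bandKind", "PredictionBand", function(x) x@kind)

#' @rdname accessors
#' @export
setMethod("bandLower", "PredictionBand", function(x) x@lower)

#' @rdname accessors
#' @export
setMethod("bandUpper", "PredictionBand", function(x) x@upper)

#' @rdname accessors
#' @export
setMethod("bandScope", "PredictionBand", function(x) x@scope)

#' @rdname accessors
#' @export
setMethod("doseValues", "PredictionBand", function(x) x@dose)

#' @rdname accessors
#' @export
setMethod("planIds", "PredictionBand", function(x) x@planIds)

## --- CoverageCurve ---------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("doseValues", "CoverageCurve", function(x) x@dose)

#' @rdname accessors
#' @export
setMethod("nPlans", "CoverageCurve", function(x) x@n)

#' @rdname accessors
#' @export
setMethod("rawCoverage", "CoverageCurve", function(x) x@raw)

#' @rdname accessors
#' @export
setMethod("smoothedCoverage", "CoverageCurve", function(x) x@smoothed)
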