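#' @importFrom methods new validObject is show setValidity slot
#' @importFrom stats approx median quantile rnorm sd shapiro.test pnorm qnorm
#' @importFrom utils read.csv write.csv
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

## ---------------------------------------------------------------------------
## DoseGrid
## ---------------------------------------------------------------------------

#' Regular dose grid in percent of prescription dose
#'
#' All cohort statistics are evaluated on a common regular dose axis expressed
#' as a percentage of the prescription (Rx) dose. The default grid spans
#' 0--110\% Rx in 1\% steps, so that the full clinical interval including and
#' beyond 100\% Rx is represented.
#'
#' @slot start,stop,step numeric scalars, \% of Rx dose; `step > 0`.
#' @aliases DoseGrid-class
#' @exportClass DoseGrid
setClass("DoseGrid",
         representation(start = "numeric", stop = "numeric", step = "numeric"))

setValidity("DoseGrid", function(object) {
  msg <- NULL
  for (s in c("start", "stop", "step")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v))
      msg <- c(msg, sprintf("'%s' must be a single finite number", s))
  }
  if (is.null(msg)) {
    if (object@step <= 0) msg <- c(msg, "'step' must be > 0")
    if (object@stop <= object@start) msg <- c(msg, "'stop' must exceed 'start'")
  }
  if (is.null(msg)) TRUE else msg
})

#' @param start,stop,step grid limits and spacing in \% of Rx dose.
#' @return A `DoseGrid` object.
#' @examples
#' g <- DoseGrid()
#' head(doseSeq(g))
#' @rdname DoseGrid-class
#' @export
DoseGrid <- function(start = 0, stop = 110, step = 1) {
  new("DoseGrid", start = as.numeric(start), stop = as.numeric(stop),
      step = as.numeric(step))
}

#' @param x a `DoseGrid`.
#' @rdname DoseGrid-class
#' @export
setGeneric("doseSeq", function(x) standardGeneric("doseSeq"))

#' @rdname DoseGrid-class
#' @export
setMethod("doseSeq", "DoseGrid", function(x) seq(x@start, x@stop, by = x@step))

setMethod("show", "DoseGrid", function(object) {
  cat(sprintf("DoseGrid: %g to %g %% Rx in steps of %g (%d points)\n",
              object@start, object@stop, object@step,
              length(doseSeq(object))))
})

## ---------------------------------------------------------------------------
## DVHCurve
## ---------------------------------------------------------------------------

#' A single cumulative dose-volume histogram
#'
#' A cumulative DVH gives, for each dose level `D` (\% of Rx dose), the
#' percentage `V(D)` of the organ's volume receiving at least `D`. Valid
#' curves are non-increasing, lie in \[0, 100\], and start at `V(0) = 100`.
#'
#' The constructor checks these cumulative-DVH semantics via
#' [validateDVH()] and refuses invalid curves unless `check = FALSE`
#' (used internally, e.g. for deliberately non-monotone simulated curves).
#'
#' @slot planId plan identifier.
#' @slot oar organ-at-risk label.
#' @slot dose strictly increasing dose axis, \% of Rx dose.
#' @slot volume volumes, \% of OAR volume, same length as `dose`.
#' @aliases DVHCurve-class
#' @exportClass DVHCurve
setClass("DVHCurve",
         representation(planId = "character", oar = "character",
                        dose = "numeric", volume = "numeric"))

setValidity("DVHCurve", function(object) {
  msg <- NULL
  if (length(object@planId) != 1L) msg <- c(msg, "'planId' must be length 1")
  if (length(object@oar) != 1L) msg <- c(msg, "'oar' must be length 1")
  if (length(object@dose) < 2L)
    msg <- c(msg, "a DVH curve needs at least 2 points")
  if (length(object@dose) != length(object@volume))
    msg <- c(msg, "'dose' and 'volume' lengths differ")
  if (anyNA(object@dose) || anyNA(object@volume) ||
      !all(is.finite(object@dose)) || !all(is.finite(object@volume)))
    msg <- c(msg, "dose and volume must be finite")
  else if (any(diff(object@dose) <= 0))
    msg <- c(msg, "'dose' must be strictly increasing")
  if (is.null(msg)) TRUE else msg
})

#' @param dose,volume numeric vectors defining the curve.
#' @param planId,oar identifying labels.
#' @param check logical; validate cumulative-DVH semantics (default `TRUE`).
#' @param tolerance volume tolerance for the `V(0) = 100` check.
#' @return A `DVHCurve`.
#' @examples
#' DVHCurve(c(0, 50, 110), c(100, 60, 0), planId = "p1", oar = "rectum")
#' @rdname DVHCurve-class
#' @export
DVHCurve <- function(dose, volume, planId = "plan", oar = "OAR",
                     check = TRUE, tolerance = 1e-6) {
  obj <- new("DVHCurve", planId = as.character(planId), oar = as.character(oar),
             dose = as.numeric(dose), volume = as.numeric(volume))
  if (check) {
    rep <- validateDVH(obj, tolerance = tolerance)
    if (!rep$pass)
      stop("invalid DVH curve for plan '", planId, "': ",
           paste(rep$violations, collapse = "; "), call. = FALSE)
  }
  obj
}

setMethod("show", "DVHCurve", function(object) {
  cat(sprintf("DVHCurve '%s' (%s): %d points, dose %g..%g %% Rx, V(min dose) = %g %%\n",
              object@planId, object@oar, length(object@dose),
              min(object@dose), max(object@dose), object@volume[1L]))
})

## ---------------------------------------------------------------------------
## DVHCohort
## ---------------------------------------------------------------------------

#' A cohort of clinical and predicted DVHs for one organ at risk
#'
#' `DVHCohort` extends [SummarizedExperiment::SummarizedExperiment]: rows are
#' dose-grid points (with `rowData()$dose_pct`), columns are plans, and the
#' assays `"clinical"` and `"predicted"` hold the matched DVH volume matrices
#' (\% OAR volume). Optional assays `"band_lower"`/`"band_upper"` carry a
#' model-provided per-plan error band; a cohort-level model band may be stored
#' in `metadata()$model_band`. `colData()$feature` optionally holds a scalar
#' anatomy-like feature per plan (used by the median-split band).
#'
#' All curves are resampled onto the common [DoseGrid] before the cohort is
#' built, so that every statistic is computed dosewise across plans.
#'
#' @aliases DVHCohort-class
#' @exportClass DVHCohort
setClass("DVHCohort", contains = "SummarizedExperiment")

setValidity("DVHCohort", function(object) {
  msg <- NULL
  an <- assayNames(object)
  if (!all(c("clinical", "predicted") %in% an))
    msg <- c(msg, "assays 'clinical' and 'predicted' are required")
  if (ncol(object) < 1L) msg <- c(msg, "cohort needs at least one plan (N >= 1)")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "plan ids (colnames) must be present and unique")
  dp <- rowData(object)$dose_pct
  if (is.null(dp) || !is.numeric(dp) || any(diff(dp) <= 0))
    msg <- c(msg, "rowData()$dose_pct must be strictly increasing")
  if (sum(c("band_lower", "band_upper") %in% an) == 1L)
    msg <- c(msg, "band assays must come in a lower/upper pair")
  for (a in intersect(c("clinical", "predicted"), an)) {
    v <- assay(object, a)
    if (anyNA(v) || any(v < -1e-6) || any(v > 100 + 1e-6))
      msg <- c(msg, sprintf("assay '%s' must lie in [0, 100]", a))
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a DVHCohort from lists of curves
#'
#' Pairs clinical and predicted [DVHCurve]s by plan id, resamples every curve
#' onto `grid` with [resampleToGrid()], and assembles the cohort object.
#'
#' @param clinical,predicted lists of [DVHCurve]s covering the same plan ids.
#' @param grid a [DoseGrid]; defaults to 0--110\% Rx in 1\% steps.
#' @param oar organ-at-risk label; taken from the curves when `NULL`.
#' @param feature optional numeric vector (or named vector) of one scalar
#'   feature per plan, e.g. an anatomy summary correlated with dose sparing.
#' @param bandLower,bandUpper optional lists of per-plan model band bound
#'   curves, matched by plan id.
#' @return A [DVHCohort].
#' @examples
#' g <- DoseGrid(0, 110, 10)
#' cl <- DVHCurve(c(0, 60, 110), c(100, 50, 0), planId = "p1")
#' pr <- DVHCurve(c(0, 55, 110), c(100, 50, 0), planId = "p1")
#' DVHCohort(list(cl), list(pr), grid = g)
#' @export
DVHCohort <- function(clinical, predicted, grid = DoseGrid(), oar = NULL,
                      feature = NULL, bandLower = NULL, bandUpper = NULL) {
  stopifnot(is.list(clinical), is.list(predicted))
  idsOf <- function(xs) vapply(xs, function(c) c@planId, character(1))
  cid <- idsOf(clinical); pid <- idsOf(predicted)
  if (anyDuplicated(cid) || anyDuplicated(pid))
    stop("duplicated plan ids within a role", call. = FALSE)
  missPred <- setdiff(cid, pid); missClin <- setdiff(pid, cid)
  if (length(missPred) || length(missClin))
    stop("pairing error: ",
         if (length(missPred))
           paste0("plans without predicted DVH: ",
                  paste(missPred, collapse = ", "), ". "),
         if (length(missClin))
           paste0("plans without clinical DVH: ",
                  paste(missClin, collapse = ", ")),
         call. = FALSE)
  ids <- cid
  if (is.null(oar)) {
    oars <- unique(c(vapply(clinical, function(c) c@oar, character(1)),
                     vapply(predicted, function(c) c@oar, character(1))))
    if (length(oars) > 1L)
      stop("curves span multiple OARs (", paste(oars, collapse = ", "),
           "); a cohort holds a single OAR", call. = FALSE)
    oar <- oars
  }
  toMat <- function(xs, ord) {
    xs <- xs[match(ids, idsOf(xs))]
    m <- vapply(xs, function(c) resampleToGrid(c, grid)@volume,
                numeric(length(doseSeq(grid))))
    m <- matrix(m, nrow = length(doseSeq(grid)), dimnames = list(NULL, ids))
    m
  }
  assays <- list(clinical = toMat(clinical), predicted = toMat(predicted))
  if (!is.null(bandLower) || !is.null(bandUpper)) {
    if (is.null(bandLower) || is.null(bandUpper))
      stop("band curves must come as a lower/upper pair", call. = FALSE)
    bl <- idsOf(bandLower); bu <- idsOf(bandUpper)
    if (!setequal(bl, ids) || !setequal(bu, ids))
      stop("pairing error: band curves must cover every plan id", call. = FALSE)
    assays$band_lower <- toMat(bandLower)
    assays$band_upper <- toMat(bandUpper)
  }
  cd <- S4Vectors::DataFrame(row.names = ids)
  if (!is.null(feature)) {
    if (!is.null(names(feature))) feature <- feature[ids]
    if (length(feature) != length(ids) || anyNA(feature))
      stop("'feature' must supply one finite value per plan", call. = FALSE)
    cd$feature <- as.numeric(feature)
  }
  new("DVHCohort",
      SummarizedExperiment(assays = assays,
                           rowData = S4Vectors::DataFrame(dose_pct = doseSeq(grid)),
                           colData = cd,
                           metadata = list(oar = oar, grid = grid)))
}

#' Assemble a DVHCohort directly from volume matrices
#'
#' Low-level constructor used by the simulator and by tests: takes
#' dose-by-plan matrices already on a common grid. Curve-level monotonicity is
#' not enforced here (pointwise-Gaussian simulated cohorts deliberately waive
#' it); matrices are only required to lie in \[0, 100\].
#'
#' @param clinical,predicted numeric matrices, dose points in rows and plans
#'   in columns, \% OAR volume.
#' @param grid the common [DoseGrid] (its `doseSeq()` must match `nrow`).
#' @param oar organ-at-risk label.
#' @param planIds plan identifiers; default `plan01, plan02, ...`.
#' @param feature optional per-plan scalar feature.
#' @param metadata extra metadata entries (list).
#' @return A [DVHCohort].
#' @export
cohortFromMatrices <- function(clinical, predicted, grid = DoseGrid(),
                               oar = "OAR", planIds = NULL, feature = NULL,
                               metadata = list()) {
  clinical <- as.matrix(clinical); predicted <- as.matrix(predicted)
  doses <- doseSeq(grid)
  stopifnot(nrow(clinical) == length(doses),
            all(dim(clinical) == dim(predicted)))
  n <- ncol(clinical)
  if (is.null(planIds)) planIds <- sprintf("plan%02d", seq_len(n))
  dimnames(clinical) <- dimnames(predicted) <- list(NULL, planIds)
  cd <- S4Vectors::DataFrame(row.names = planIds)
  if (!is.null(feature)) cd$feature <- as.numeric(feature)
  md <- c(list(oar = oar, grid = grid), metadata)
  new("DVHCohort",
      SummarizedExperiment(assays = list(clinical = clinical,
                                         predicted = predicted),
                           rowData = S4Vectors::DataFrame(dose_pct = doses),
                           colData = cd, metadata = md))
}

setMethod("show", "DVHCohort", function(object) {
  cat(sprintf("DVHCohort: %d plans x %d dose points, OAR '%s'\n",
              ncol(object), nrow(object), oarLabel(object)))
  cat(sprintf("  dose grid: %g..%g %% Rx\n",
              min(doseValues(object)), max(doseValues(object))))
  cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
  if (!is.null(metadata(object)$monotone_waived) &&
      isTRUE(metadata(object)$monotone_waived))
    cat("  note: pointwise-noise cohort, curve monotonicity waived\n")
})

## ---------------------------------------------------------------------------
## ErrorSummary
## ---------------------------------------------------------------------------

#' Dosewise prediction-error summary
#'
#' Per dose point, across the cohort of prediction errors
#' `e_i(D) = V_clin,i(D) - V_pred,i(D)`:
#' bias `mu(D)` (mean error), error variation `sigma(D)` (sample SD, N-1
#' denominator), its population counterpart `sigmaPop(D)` (N denominator),
#' and the root-mean-square error `rmse(D)`. These obey
#' `rmse^2 = mu^2 + sigmaPop^2` exactly, and approximately with the sample SD
#' (see [quadratureCheck()]).
#'
#' @slot dose dose axis, \% Rx.
#' @slot mu,sigma,sigmaPop,rmse per-dose statistics, \% OAR volume; `sigma`
#'   is `NA` for single-plan cohorts.
#' @slot n plan count.
#' @aliases ErrorSummary-class
#' @exportClass ErrorSummary
setClass("ErrorSummary",
         representation(dose = "numeric", mu = "numeric", sigma = "numeric",
                        sigmaPop = "numeric", rmse = "numeric", n = "integer"))

setValidity("ErrorSummary", function(object) {
  len <- length(object@dose)
  msg <- NULL
  if (!all(lengths(list(object@mu, object@sigma, object@sigmaPop,
                        object@rmse)) == len))
    msg <- c(msg, "all per-dose vectors must share the dose axis length")
  if (length(object@n) != 1L || object@n < 1L)
    msg <- c(msg, "'n' must be a single count >= 1")
  if (is.null(msg) && any(object@rmse + 1e-9 < abs(object@mu)))
    msg <- c(msg, "rmse(D) must be >= |mu(D)|")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "ErrorSummary", function(object) {
  cat(sprintf("ErrorSummary over %d plans, %d dose points\n",
              object@n, length(object@dose)))
  cat(sprintf("  |mu| max %.3f, sigma max %.3f, RMSE max %.3f (%% OAR volume)\n",
              max(abs(object@mu)), suppressWarnings(max(object@sigma)),
              max(object@rmse)))
})

#' @describeIn ErrorSummary-class coerce to a data.frame with columns
#'   `dose_pct, mu, sigma, sigma_pop, rmse, n`.
#' @param x an `ErrorSummary`.
#' @param ... ignored.
#' @export
as.data.frame.ErrorSummary <- function(x, ...) {
  data.frame(dose_pct = x@dose, mu = x@mu, sigma = x@sigma,
             sigma_pop = x@sigmaPop, rmse = x@rmse, n = x@n)
}

## ---------------------------------------------------------------------------
## PredictionBand
## ---------------------------------------------------------------------------

#' Lower/upper DVH error-band bounds
#'
#' Holds the bound curves of one error-band formalism. Per-plan bands
#' (`scope = "plan"`) store one lower/upper column per plan; cohort-level
#' bands (`scope = "cohort"`) store single columns applying to every plan.
#' Bounds are clipped to \[0, 100\] but deliberately not re-monotonized: the
#' coverage tally is pointwise, and re-monotonizing would silently change it.
#'
#' @slot kind one of `"rmse"`, `"iqr"`, `"median_split"`, `"model_provided"`.
#' @slot dose dose axis, \% Rx.
#' @slot lower,upper matrices (dose points x 1 or x N plans), \% OAR volume.
#' @slot scope `"cohort"` or `"plan"`.
#' @slot planIds plan ids for per-plan scope (empty for cohort scope).
#' @slot symmetric logical; for model-provided bands, whether
#'   `upper - predicted == predicted - lower` everywhere. `NA` otherwise.
#' @aliases PredictionBand-class
#' @exportClass PredictionBand
setClass("PredictionBand",
         representation(kind = "character", dose = "numeric",
                        lower = "matrix", upper = "matrix",
                        scope = "character", planIds = "character",
                        symmetric = "logical"))

setValidity("PredictionBand", function(object) {
  msg <- NULL
  if (!object@kind %in% c("rmse", "iqr", "median_split", "model_provided"))
    msg <- c(msg, "unknown band kind")
  if (!object@scope %in% c("cohort", "plan"))
    msg <- c(msg, "scope must be 'cohort' or 'plan'")
  if (nrow(object@lower) != length(object@dose) ||
      !all(dim(object@lower) == dim(object@upper)))
    msg <- c(msg, "bound matrices must match the dose axis and each other")
  else {
    if (any(object@lower > object@upper + 1e-9))
      msg <- c(msg, "lower bound exceeds upper bound")
    if (any(object@lower < -1e-9) || any(object@upper > 100 + 1e-9))
      msg <- c(msg, "bounds must lie in [0, 100]")
  }
  if (object@scope == "plan" && length(object@planIds) != ncol(object@lower))
    msg <- c(msg, "per-plan band needs one column per plan id")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "PredictionBand", function(object) {
  cat(sprintf("PredictionBand '%s' (%s scope): %d dose points%s\n",
              object@kind, object@scope, length(object@dose),
              if (object@scope == "plan")
                sprintf(", %d plans", ncol(object@lower)) else ""))
  w <- object@upper - object@lower
  cat(sprintf("  mean half-width %.3f %% OAR volume\n", mean(w) / 2))
})

## ---------------------------------------------------------------------------
## CoverageCurve
## ---------------------------------------------------------------------------

#' Dosewise prediction success rate
#'
#' At each dose point, the fraction of plans whose clinical DVH value is
#' tallied as correctly predicted (inside the band, or within the volume
#' tolerance of the prediction), raw and boxcar-smoothed.
#'
#' @slot dose dose axis, \% Rx.
#' @slot raw,smoothed per-dose success fractions in \[0, 1\].
#' @slot window odd boxcar window length (points).
#' @slot tolerance volume tolerance, \% OAR volume.
#' @slot n plan count.
#' @slot kind band kind the curve was computed for.
#' @aliases CoverageCurve-class
#' @exportClass CoverageCurve
setClass("CoverageCurve",
         representation(dose = "numeric", raw = "numeric", smoothed = "numeric",
                        window = "integer", tolerance = "numeric",
                        n = "integer", kind = "character"))

setValidity("CoverageCurve", function(object) {
  msg <- NULL
  if (length(object@raw) != length(object@dose) ||
      length(object@smoothed) != length(object@dose))
    msg <- c(msg, "curve vectors must share the dose axis length")
  if (any(object@raw < -1e-12 | object@raw > 1 + 1e-12))
    msg <- c(msg, "raw fractions must lie in [0, 1]")
  if (object@window %% 2L == 0L) msg <- c(msg, "'window' must be odd")
  if (object@tolerance < 0) msg <- c(msg, "'tolerance' must be >= 0")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "CoverageCurve", function(object) {
  cat(sprintf(
    "CoverageCurve (%s band, n = %d, tolerance %g%%, %d-point boxcar)\n",
    object@kind, object@n, object@tolerance, object@window))
  cat(sprintf("  smoothed success: %.1f..%.1f%% (mean %.1f%%)\n",
              100 * min(object@smoothed), 100 * max(object@smoothed),
              100 * mean(object@smoothed)))
})

#' @describeIn CoverageCurve-class coerce to a data.frame with columns
#'   `dose_pct, raw, smoothed`.
#' @param x a `CoverageCurve`.
#' @param ... ignored.
#' @export
as.data.frame.CoverageCurve <- function(x, ...) {
  data.frame(dose_pct = x@dose, raw = x@raw, smoothed = x@smoothed)
}
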