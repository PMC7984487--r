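## Construction of the competing error-band formalisms: empirical +/- RMSE,
## percentile (IQR), median-split (ORBIT-RT style), and model-provided bands.

.clip01 <- function(m) pmin(pmax(m, 0), 100)

.makeBand <- function(kind, dose, lower, upper, scope, planIds = character(0),
                      symmetric = NA) {
  new("PredictionBand", kind = kind, dose = as.numeric(dose),
      lower = lower, upper = upper, scope = scope,
      planIds = as.character(planIds), symmetric = as.logical(symmetric))
}

#' Empirical V_pred +/- RMSE_pred band
#'
#' The model-independent error band: each plan's predicted DVH plus and minus
#' the cohort RMSE_pred(D), clipped to \[0, 100\]. The width is shared across
#' the cohort; the band is centered on each plan's own prediction (per-plan
#' scope). When the prediction bias is near zero, RMSE_pred behaves as a
#' canonical standard deviation, so this band is expected to cover about 68\%
#' of normally distributed clinical DVHs.
#'
#' @param cohort a [DVHCohort].
#' @param summary an [ErrorSummary] on the cohort's grid; computed from
#'   `cohort` when omitted.
#' @return A per-plan [PredictionBand] of kind `"rmse"`.
#' @export
rmseBand <- function(cohort, summary = NULL) {
  stopifnot(is(cohort, "DVHCohort"))
  if (is.null(summary)) summary <- summarizeErrors(cohort)
  if (!isTRUE(all.equal(doseValues(cohort), summary@dose)))
    stop("alignment error: cohort and error summary use different dose grids",
         call. = FALSE)
  pred <- predictedVolumes(cohort)
  .makeBand("rmse", summary@dose,
            .clip01(pred - summary@rmse), .clip01(pred + summary@rmse),
            scope = "plan", planIds = colnames(pred))
}

#' Interquartile-range band of the clinical DVH distribution
#'
#' At each dose point, the band spans the 25th to 75th percentile of the
#' cohort's clinical volumes (linear interpolation between order statistics,
#' `quantile()` type 7). Such a band covers 50\% of the generating
#' distribution by construction.
#'
#' @param cohort a [DVHCohort] with at least 2 plans.
#' @param probs lower/upper percentile pair, default `c(0.25, 0.75)`.
#' @return A cohort-scope [PredictionBand] of kind `"iqr"`.
#' @export
iqrBand <- function(cohort, probs = c(0.25, 0.75)) {
  stopifnot(is(cohort, "DVHCohort"))
  if (nPlans(cohort) < 2L)
    stop("IQR band is undefined for a single-plan cohort", call. = FALSE)
  stopifnot(length(probs) == 2L, probs[1] < probs[2])
  clin <- clinicalVolumes(cohort)
  qs <- t(apply(clin, 1L, quantile, probs = probs, type = 7, names = FALSE))
  .makeBand("iqr", doseValues(cohort),
            .clip01(cbind(qs[, 1])), .clip01(cbind(qs[, 2])),
            scope = "cohort")
}

#' Median-split band over a matching feature
#'
#' Emulates the ORBIT-RT error-band formalism generically: plans are split at
#' the median of a scalar matching feature into a \[min, median\] and a
#' \[median, max\] half (for odd cohorts the median plan joins both halves),
#' and the mean clinical DVH of each half provides one bound. The bound
#' orientation is resolved pointwise — at each dose the upper bound is the
#' larger of the two half-means — because the feature/DVH correlation can
#' change sign along the dose axis.
#'
#' With `pointwise = TRUE` the split is re-done at every dose point using the
#' clinical volumes at that dose as the feature (the self-matching limit used
#' for closed-form calibration: under pointwise Gaussian errors the band
#' half-width tends to `sqrt(2/pi) * sigma`, the mean of a half-normal, so
#' expected coverage is `2 * pnorm(sqrt(2/pi)) - 1`, about 57.5\%).
#'
#' @param cohort a [DVHCohort] with at least 2 plans.
#' @param feature one finite scalar per plan; defaults to
#'   `planFeature(cohort)`. Ignored when `pointwise = TRUE`.
#' @param pointwise split at each dose point on the dosewise clinical values.
#' @return A cohort-scope [PredictionBand] of kind `"median_split"`.
#' @export
medianSplitBand <- function(cohort, feature = NULL, pointwise = FALSE) {
  stopifnot(is(cohort, "DVHCohort"))
  n <- nPlans(cohort)
  if (n < 2L)
    stop("median-split band needs at least 2 plans", call. = FALSE)
  clin <- clinicalVolumes(cohort)

  halves <- function(f) {
    if (max(f) == min(f)) {
      ## degenerate: no feature ordering; stable split by plan order
      lo <- seq_len(ceiling(n / 2)); hi <- seq.int(floor(n / 2) + 1L, n)
      return(list(lo = lo, hi = hi, degenerate = TRUE))
    }
    med <- median(f)
    list(lo = which(f <= med), hi = which(f >= med), degenerate = FALSE)
  }
  if (pointwise) {
    bounds <- t(apply(clin, 1L, function(v) {
      h <- halves(v)
      mm <- c(mean(v[h$lo]), mean(v[h$hi]))
      c(min(mm), max(mm))
    }))
  } else {
    if (is.null(feature)) feature <- planFeature(cohort)
    if (is.null(feature))
      stop("no per-plan feature available; supply 'feature' or set ",
           "colData(cohort)$feature", call. = FALSE)
    feature <- as.numeric(feature)
    if (length(feature) != n || anyNA(feature) || !all(is.finite(feature)))
      stop("'feature' must supply one finite value per plan", call. = FALSE)
    h <- halves(feature)
    if (h$degenerate)
      warning("all feature values identical: degenerate split by plan order",
              call. = FALSE)
    mL <- rowMeans(clin[, h$lo, drop = FALSE])
    mU <- rowMeans(clin[, h$hi, drop = FALSE])
    bounds <- cbind(pmin(mL, mU), pmax(mL, mU))
  }
  .makeBand("median_split", doseValues(cohort),
            .clip01(cbind(bounds[, 1])), .clip01(cbind(bounds[, 2])),
            scope = "cohort")
}

#' Ingest a model-provided symmetric error band
#'
#' Extracts (or builds) a model-provided per-plan band and checks its
#' integrity: after clipping to \[0, 100\], the bounds must satisfy
#' `lower <= predicted <= upper` at every dose point, otherwise an error
#' lists the offending dose points. A symmetry flag records whether
#' `upper - predicted` equals `predicted - lower` everywhere (the
#' added-and-subtracted construction some models use).
#'
#' @param cohort a [DVHCohort] whose `band_lower`/`band_upper` assays hold the
#'   model band (e.g. loaded by [readCohort()]), or `NULL` when `lower`,
#'   `upper` and `predicted` matrices are given directly.
#' @param lower,upper,predicted dose-by-plan matrices when building directly.
#' @param dose dose axis for direct construction.
#' @param tolerance slack for the integrity and symmetry comparisons.
#' @return A per-plan [PredictionBand] of kind `"model_provided"`; slot
#'   `symmetric` records the symmetry flag.
#' @export
modelBand <- function(cohort = NULL, lower = NULL, upper = NULL,
                      predicted = NULL, dose = NULL, tolerance = 1e-6) {
  if (!is.null(cohort)) {
    stopifnot(is(cohort, "DVHCohort"))
    if (!all(c("band_lower", "band_upper") %in% assayNames(cohort))) {
      mb <- metadata(cohort)$model_band
      if (!is.null(mb)) return(mb)
      stop("cohort carries no model-provided band", call. = FALSE)
    }
    lower <- assay(cohort, "band_lower")
    upper <- assay(cohort, "band_upper")
    predicted <- predictedVolumes(cohort)
    dose <- doseValues(cohort)
  }
  lower <- .clip01(as.matrix(lower)); upper <- .clip01(as.matrix(upper))
  predicted <- as.matrix(predicted)
  stopifnot(all(dim(lower) == dim(upper)),
            all(dim(lower) == dim(predicted)),
            nrow(lower) == length(dose))
  bad <- which(lower > upper + tolerance |
                 lower > predicted + tolerance |
                 predicted > upper + tolerance, arr.ind = TRUE)
  if (nrow(bad))
    stop("band-integrity error: bounds cross the prediction at dose point(s) ",
         paste(unique(dose[bad[, 1L]]), collapse = ", "), call. = FALSE)
  symmetric <- all(abs((upper - predicted) - (predicted - lower)) <= tolerance)
  ids <- colnames(predicted)
  if (is.null(ids)) ids <- sprintf("plan%02d", seq_len(ncol(predicted)))
  .makeBand("model_provided", dose, lower, upper, scope = "plan",
            planIds = ids, symmetric = symmetric)
}

#' Widen a band pointwise (utility)
#'
#' Adds `delta` (\% OAR volume, recycled over dose points) to the upper bound
#' and subtracts it from the lower bound, re-clipping to \[0, 100\]. Coverage
#' is monotone non-decreasing under this operation.
#'
#' @param band a [PredictionBand].
#' @param delta non-negative widening, \% OAR volume.
#' @return A [PredictionBand] of the same kind and scope.
#' @export
widenBand <- function(band, delta) {
  stopifnot(is(band, "PredictionBand"), all(delta >= 0))
  .makeBand(band@kind, band@dose,
            .clip01(band@lower - delta), .clip01(band@upper + delta),
            scope = band@scope, planIds = band@planIds,
            symmetric = band@symmetric)
}
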