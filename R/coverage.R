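## Prediction-success tally: pointwise band membership with a clinical volume
## tolerance, boxcar smoothing, and dose-range summaries.

#' Tally rule for a single dose point
#'
#' A clinical value is tallied as correctly predicted when it lies inside the
#' band, or when it lies strictly within `tolerance` \% of OAR volume of the
#' prediction itself (clinically irrelevant dose-volume granularity). The
#' tolerance comparison is strict (`<`) and is measured to the prediction,
#' not to the nearer band edge. Vectorized over its arguments.
#'
#' @param clinical,predicted clinical and predicted volumes, \% OAR volume.
#' @param lower,upper band bounds, \% OAR volume.
#' @param tolerance non-negative volume tolerance, default 0.5 \%.
#' @return Logical vector of successes.
#' @examples
#' pointWithinBand(50.4, 50, 49.8, 50.2)   # caught by the 0.5% tolerance
#' pointWithinBand(51.0, 50, 49.8, 50.2)   # failure
#' @export
pointWithinBand <- function(clinical, predicted, lower, upper,
                            tolerance = 0.5) {
  stopifnot(tolerance >= 0)
  if (any(lower > upper + 1e-9))
    stop("band-integrity error: lower bound exceeds upper bound",
         call. = FALSE)
  (lower <= clinical & clinical <= upper) |
    (abs(clinical - predicted) < tolerance)
}

#' Centered boxcar (moving-average) smoothing
#'
#' Unweighted centered moving average with an odd window. At the series
#' edges the window shrinks symmetrically to fit, so no data are invented by
#' padding; `window = 1` is the identity.
#'
#' @param x numeric series.
#' @param window odd window length in points, `1 <= window <= length(x)`.
#' @return Smoothed numeric series of the same length.
#' @examples
#' boxcarSmooth(c(rep(0, 10), 1, rep(0, 10)), 11)
#' @export
boxcarSmooth <- function(x, window = 11L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("'window' must be an odd positive integer", call. = FALSE)
  n <- length(x)
  if (window > n)
    stop("'window' exceeds the series length", call. = FALSE)
  half <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    k <- min(half, i - 1L, n - i)
    mean(x[(i - k):(i + k)])
  }, numeric(1))
}

#' Dosewise prediction-success curve
#'
#' At every grid dose independently, tallies the fraction of plans whose
#' clinical DVH value is correctly predicted by the band (see
#' [pointWithinBand()]), and applies boxcar smoothing. Cohort-scope bands
#' apply the same bounds to every plan; per-plan bands are matched to plans
#' by id.
#'
#' @param cohort a [DVHCohort].
#' @param band a [PredictionBand] on the same dose grid.
#' @param tolerance volume tolerance of the tally rule, \% OAR volume
#'   (default 0.5; set 0 for calibration against closed forms).
#' @param window odd boxcar window, default 11 points.
#' @return A [CoverageCurve].
#' @export
coverageCurve <- function(cohort, band, tolerance = 0.5, window = 11L) {
  stopifnot(is(cohort, "DVHCohort"), is(band, "PredictionBand"))
  if (!isTRUE(all.equal(doseValues(cohort), band@dose)))
    stop("alignment error: cohort and band use different dose grids",
         call. = FALSE)
  clin <- clinicalVolumes(cohort)
  pred <- predictedVolumes(cohort)
  n <- ncol(clin)
  if (band@scope == "plan") {
    if (!setequal(band@planIds, colnames(clin)))
      stop("pairing error: band plans ",
           paste(setdiff(colnames(clin), band@planIds), collapse = ", "),
           " missing", call. = FALSE)
    ord <- match(colnames(clin), band@planIds)
    lower <- band@lower[, ord, drop = FALSE]
    upper <- band@upper[, ord, drop = FALSE]
  } else {
    lower <- band@lower[, rep(1L, n), drop = FALSE]
    upper <- band@upper[, rep(1L, n), drop = FALSE]
  }
  ok <- pointWithinBand(clin, pred, lower, upper, tolerance)
  raw <- rowMeans(ok)
  new("CoverageCurve", dose = doseValues(cohort), raw = raw,
      smoothed = boxcarSmooth(raw, window), window = as.integer(window),
      tolerance = tolerance, n = as.integer(n), kind = band@kind)
}

#' Summarize a coverage curve over a dose range
#'
#' Reports the minimum, maximum and mean prediction success (in percent) of
#' the smoothed (default) or raw curve over a dose range.
#'
#' @param curve a [CoverageCurve].
#' @param range dose range `c(lo, hi)` in \% Rx, inclusive; defaults to the
#'   full grid.
#' @param use `"smoothed"` (default) or `"raw"`.
#' @return A list with `min`, `max`, `mean` in percent, plus the range used.
#' @export
coverageSummary <- function(curve, range = NULL,
                            use = c("smoothed", "raw")) {
  stopifnot(is(curve, "CoverageCurve"))
  use <- match.arg(use)
  if (is.null(range)) range <- range(curve@dose)
  if (length(range) != 2L || range[1] > range[2])
    stop("'range' must be c(lo, hi) with lo <= hi", call. = FALSE)
  sel <- curve@dose >= range[1] & curve@dose <= range[2]
  if (!any(sel)) stop("empty dose range", call. = FALSE)
  v <- 100 * slot(curve, use)[sel]
  list(min = min(v), max = max(v), mean = mean(v), range = range, use = use)
}

#' Export a coverage curve to CSV
#'
#' Columns `dose_pct, raw, smoothed`.
#'
#' @param curve a [CoverageCurve].
#' @param file output path, or `NULL` to return the data.frame.
#' @return The data.frame, invisibly when `file` is given.
#' @export
writeCoverageCurve <- function(curve, file = NULL) {
  df <- as.data.frame(curve)
  if (is.null(file)) return(df)
  write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(df)
}
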