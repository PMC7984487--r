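## Orchestration: full validation runs from a cohort table, and Monte-Carlo
## calibration of the band formalisms against their closed-form coverages.

#' Run the full DVH prediction validation pipeline
#'
#' Pipeline: read (or accept) a cohort, summarize dosewise errors, check the
#' quadrature relation, build the requested error bands, tally each band's
#' coverage curve, and summarize coverage over a dose range. Optionally
#' writes a report bundle: `error_summary.csv`, one `coverage_<kind>.csv` per
#' band, a `manifest.json` recording the configuration, and (with
#' `plots = TRUE`) PDF panels of the error statistics and coverage curves.
#' On failure, partially written outputs are removed.
#'
#' @param cohort a [DVHCohort], or a path to a long-format CSV for
#'   [readCohort()].
#' @param bandKinds subset of `c("rmse", "iqr", "median_split",
#'   "model_provided")`; kinds whose prerequisites are missing (no feature,
#'   no model band) are skipped with a warning.
#' @param tolerance tally tolerance, \% OAR volume (default 0.5).
#' @param window odd boxcar window (default 11); validated before any
#'   computation.
#' @param summaryRange dose range for [coverageSummary()]; default full grid.
#' @param feature per-plan feature for the median-split band; default
#'   `planFeature(cohort)`.
#' @param outDir directory for the report bundle, or `NULL` for none.
#' @param plots write PDF figures into `outDir`.
#' @return A list: `cohort`, `errorSummary`, `quadrature`, `bands`,
#'   `coverage` (per kind), `summaries` (per kind, percent), `config`.
#' @export
runValidation <- function(cohort,
                          bandKinds = c("rmse", "iqr", "median_split"),
                          tolerance = 0.5, window = 11L, summaryRange = NULL,
                          feature = NULL, outDir = NULL, plots = FALSE) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("'window' must be an odd positive integer", call. = FALSE)
  if (tolerance < 0) stop("'tolerance' must be >= 0", call. = FALSE)
  bandKinds <- match.arg(bandKinds,
                         c("rmse", "iqr", "median_split", "model_provided"),
                         several.ok = TRUE)
  if (is.character(cohort)) cohort <- readCohort(cohort)
  stopifnot(is(cohort, "DVHCohort"))

  written <- character(0)
  res <- tryCatch({
    es <- summarizeErrors(cohort)
    qc <- quadratureCheck(es)
    bands <- list()
    for (kind in bandKinds) {
      b <- switch(kind,
        rmse = rmseBand(cohort, es),
        iqr = iqrBand(cohort),
        median_split = {
          f <- if (is.null(feature)) planFeature(cohort) else feature
          if (is.null(f)) {
            warning("no per-plan feature: skipping median_split band",
                    call. = FALSE); NULL
          } else medianSplitBand(cohort, feature = f)
        },
        model_provided = {
          ok <- all(c("band_lower", "band_upper") %in% assayNames(cohort)) ||
            !is.null(metadata(cohort)$model_band)
          if (!ok) {
            warning("no model-provided band in cohort: skipping",
                    call. = FALSE); NULL
          } else modelBand(cohort)
        })
      if (!is.null(b)) bands[[kind]] <- b
    }
    coverage <- lapply(bands, function(b)
      coverageCurve(cohort, b, tolerance = tolerance, window = window))
    summaries <- lapply(coverage, function(cc)
      coverageSummary(cc, range = summaryRange))
    config <- list(bandKinds = names(bands), tolerance = tolerance,
                   window = window,
                   summaryRange = summaryRange %||% range(doseValues(cohort)),
                   n = nPlans(cohort), oar = oarLabel(cohort))

    if (!is.null(outDir)) {
      dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
      p <- file.path(outDir, "error_summary.csv")
      writeErrorSummary(es, p); written <- c(written, p)
      for (kind in names(coverage)) {
        p <- file.path(outDir, sprintf("coverage_%s.csv", kind))
        writeCoverageCurve(coverage[[kind]], p); written <- c(written, p)
      }
      p <- file.path(outDir, "manifest.json")
      jsonlite::write_json(
        list(config = config, quadrature = qc,
             coverage_summaries = summaries),
        p, auto_unbox = TRUE, digits = NA)
      written <- c(written, p)
      if (plots) {
        p <- file.path(outDir, "error_summary.pdf")
        ggplot2::ggsave(p, plotErrorSummary(es), width = 7, height = 4)
        written <- c(written, p)
        for (kind in names(coverage)) {
          p <- file.path(outDir, sprintf("coverage_%s.pdf", kind))
          ggplot2::ggsave(p, plotCoverage(coverage[[kind]]),
                          width = 7, height = 4)
          written <- c(written, p)
        }
      }
    }
    list(cohort = cohort, errorSummary = es, quadrature = qc, bands = bands,
         coverage = coverage, summaries = summaries, config = config)
  }, error = function(e) {
    unlink(written)
    stop(e)
  })
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Monte-Carlo calibration of band coverages against closed forms
#'
#' Simulates a pointwise-Gaussian cohort (zero bias), builds each requested
#' band, and compares its mean raw coverage over the interior dose range
#' (tolerance 0 by default) with the closed-form expectation for normal
#' errors:
#' \itemize{
#'   \item `rmse`: `2*pnorm(1) - 1` = 68.27\% (a one-sigma band);
#'   \item `iqr`: 50\% (by definition of quartiles);
#'   \item `median_split` (pointwise self-matching feature):
#'     `2*pnorm(sqrt(2/pi)) - 1` = 57.51\% (half-normal mean half-width).
#' }
#' The ladder orders the formalisms: IQR < median-split < one-sigma.
#'
#' @param n simulated plan count (default 2000).
#' @param spread dosewise error SD, \% volume (default 3).
#' @param seed integer seed.
#' @param bands which band kinds to calibrate.
#' @param tolerance tally tolerance (default 0 so the closed forms apply).
#' @param interior dose range over which coverage is averaged.
#' @param mcTol acceptance half-width in percentage points (default 2).
#' @param grid the [DoseGrid].
#' @return A list with `table` (kind, observed and expected coverage in
#'   percent, pass flag) and the simulated `cohort`.
#' @examples
#' \donttest{
#' runCalibration(n = 500, seed = 1)$table
#' }
#' @export
runCalibration <- function(n = 2000, spread = 3, seed = 1,
                           bands = c("rmse", "iqr", "median_split"),
                           tolerance = 0, interior = c(20, 90), mcTol = 2,
                           grid = DoseGrid()) {
  bands <- match.arg(bands, c("rmse", "iqr", "median_split"),
                     several.ok = TRUE)
  co <- simulateCohort(syntheticSpec(n = n, grid = grid, bias = 0,
                                     spread = spread, mode = "pointwise",
                                     seed = seed))
  expected <- c(rmse = 100 * (2 * pnorm(1) - 1),
                iqr = 50,
                median_split = 100 * (2 * pnorm(sqrt(2 / pi)) - 1))
  obs <- vapply(bands, function(kind) {
    b <- switch(kind,
                rmse = rmseBand(co),
                iqr = iqrBand(co),
                median_split = medianSplitBand(co, pointwise = TRUE))
    cc <- coverageCurve(co, b, tolerance = tolerance, window = 1L)
    coverageSummary(cc, range = interior, use = "raw")$mean
  }, numeric(1))
  tab <- data.frame(kind = bands, observed = obs,
                    expected = expected[bands],
                    pass = abs(obs - expected[bands]) <= mcTol,
                    row.names = NULL)
  list(table = tab, n = n, interior = interior, tolerance = tolerance,
       cohort = co)
}

#' Plot dosewise bias, variation and RMSE
#'
#' Bias `mu(D)` as a curve with a symmetric `+/- sigma(D)` ribbon, and
#' `RMSE_pred(D)` as a separate curve.
#'
#' @param summary an [ErrorSummary].
#' @return A ggplot object.
#' @export
plotErrorSummary <- function(summary) {
  df <- as.data.frame(summary)
  ggplot2::ggplot(df, ggplot2::aes(x = dose_pct)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = mu - sigma, ymax = mu + sigma),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = mu), color = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = rmse), color = "firebrick",
                       linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::labs(x = "Dose (% Rx)",
                  y = "Prediction error (% OAR volume)",
                  title = "Bias mu +/- sigma (ribbon) and RMSE_pred (dashed)") +
    ggplot2::theme_minimal()
}

#' Plot a prediction-success curve
#'
#' Raw dosewise success fractions as points with the boxcar-smoothed curve
#' overlaid, in percent.
#'
#' @param curve a [CoverageCurve].
#' @return A ggplot object.
#' @export
plotCoverage <- function(curve) {
  df <- as.data.frame(curve)
  ggplot2::ggplot(df, ggplot2::aes(x = dose_pct)) +
    ggplot2::geom_point(ggplot2::aes(y = 100 * raw), size = 0.6,
                        color = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = 100 * smoothed), color = "steelblue") +
    ggplot2::labs(x = "Dose (% Rx)", y = "Prediction success (%)",
                  title = sprintf("Coverage of the %s band (n = %d)",
                                  curve@kind, curve@n)) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}
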