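## Dosewise prediction-error statistics: bias, variation, RMSE and the
## quadrature identity RMSE^2 = mu^2 + sigma^2.

#' Per-plan, per-dose prediction errors
#'
#' Errors follow the clinical-minus-predicted sign convention:
#' `e_i(D) = V_clin,i(D) - V_pred,i(D)`, so a positive error means the
#' clinical volume lies above the prediction (the model underpredicted the
#' dose to the organ), and negative means overprediction.
#'
#' @param cohort a [DVHCohort] (clinical and predicted assays share the grid
#'   by construction).
#' @return A numeric matrix, dose points in rows and plans in columns,
#'   \% OAR volume.
#' @export
dosewiseErrors <- function(cohort) {
  stopifnot(is(cohort, "DVHCohort"))
  clinicalVolumes(cohort) - predictedVolumes(cohort)
}

#' Summarize dosewise prediction errors
#'
#' Per dose point, computes the prediction bias `mu(D)` (mean error), the
#' error variation `sigma(D)` (sample standard deviation, N-1 denominator),
#' its population counterpart `sigmaPop(D)` (N denominator), and the
#' root-mean-square prediction error
#' `rmse(D) = sqrt(mean(e_i(D)^2))`. By construction
#' `rmse^2 = mu^2 + sigmaPop^2` holds exactly; with the sample SD the
#' relation holds approximately, the deficit being `sigma^2 / n`.
#'
#' For a single-plan cohort `mu` and `rmse` are defined, `sigma` is reported
#' as missing (`NA`, not 0 — a silent zero would fake certainty) and
#' `sigmaPop` is 0; a warning is raised.
#'
#' @param x a [DVHCohort], or an error matrix as from [dosewiseErrors()]
#'   (dose points in rows, plans in columns).
#' @param dose dose axis when `x` is a matrix; defaults to the row index.
#' @return An [ErrorSummary].
#' @examples
#' e <- matrix(c(1, -1, 2), nrow = 1)  # three plans, one dose point
#' es <- summarizeErrors(e)
#' c(mu = errorBias(es), rmse = errorRMSE(es), sigma = errorSD(es))
#' @export
summarizeErrors <- function(x, dose = NULL) {
  if (is(x, "DVHCohort")) {
    dose <- doseValues(x)
    x <- dosewiseErrors(x)
  }
  x <- as.matrix(x)
  if (!length(x)) stop("empty error matrix", call. = FALSE)
  n <- ncol(x)
  if (is.null(dose)) dose <- seq_len(nrow(x))
  mu <- rowMeans(x)
  rmse <- sqrt(rowMeans(x^2))
  dev2 <- rowSums((x - mu)^2)
  sigmaPop <- sqrt(dev2 / n)
  if (n >= 2L) {
    sigma <- sqrt(dev2 / (n - 1L))
  } else {
    warning("single-plan cohort: sigma is undefined (reported as NA)",
            call. = FALSE)
    sigma <- rep(NA_real_, nrow(x))
  }
  new("ErrorSummary", dose = as.numeric(dose), mu = mu, sigma = sigma,
      sigmaPop = sigmaPop, rmse = rmse, n = as.integer(n))
}

#' Check the quadrature relation RMSE^2 = mu^2 + sigma^2
#'
#' With the population variance the identity is algebraically exact; with the
#' sample (N-1) variance it holds only approximately, the residual being
#' exactly `sigma^2 / n`, which is bounded by `sigma^2 / (n - 1)`. Both
#' residuals are reported, maximized over dose.
#'
#' @param summary an [ErrorSummary] with `n >= 2`.
#' @return A list: `max_pop_residual` and `max_pop_residual_rel`
#'   (absolute/relative residual of `rmse^2 - (mu^2 + sigmaPop^2)`),
#'   `max_sample_residual`, its bound `sample_bound = max(sigma^2) / (n - 1)`,
#'   and logical `pass`.
#' @export
quadratureCheck <- function(summary) {
  stopifnot(is(summary, "ErrorSummary"))
  if (summary@n < 2L)
    stop("quadrature check needs n >= 2 (sigma undefined otherwise)",
         call. = FALSE)
  popRes <- abs(summary@rmse^2 - (summary@mu^2 + summary@sigmaPop^2))
  scale <- pmax(summary@rmse^2, .Machine$double.eps)
  sampRes <- abs(summary@rmse^2 - (summary@mu^2 + summary@sigma^2))
  bound <- max(summary@sigma^2) / (summary@n - 1L)
  out <- list(max_pop_residual = max(popRes),
              max_pop_residual_rel = max(popRes / scale),
              max_sample_residual = max(sampRes),
              sample_bound = bound,
              pass = max(popRes / scale) < 1e-9 &&
                all(sampRes <= bound + 1e-9))
  out
}

#' Export an error summary to CSV
#'
#' Columns `dose_pct, mu, sigma, sigma_pop, rmse, n`.
#'
#' @param summary an [ErrorSummary].
#' @param file output path, or `NULL` to return the data.frame.
#' @return The data.frame, invisibly when `file` is given.
#' @export
writeErrorSummary <- function(summary, file = NULL) {
  df <- as.data.frame(summary)
  if (is.null(file)) return(df)
  write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(df)
}
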