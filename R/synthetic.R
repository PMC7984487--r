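## Synthetic reference cohorts with known injected bias and spread, so every
## statistic and coverage calibration is testable without institutional data.

#' Specification of a synthetic DVH cohort
#'
#' Plans are sigmoid cumulative DVHs: `V(D) = 100 * s(D) / s(0)` with
#' `s(D) = 1 / (1 + exp((D - d50) / k))`, normalized so `V(0) = 100`
#' exactly. Each plan draws its midpoint `d50 ~ N(d50Mean, d50SD)`; the drawn
#' `d50` doubles as the plan's anatomy-like matching feature (larger `d50` =
#' less sparing). Prediction errors are injected on top of the predicted
#' curve in one of two modes:
#'
#' * `"pointwise"` — clinical = predicted + `bias(D)` + `e_i(D)` with
#'   `e_i(D) ~ N(0, spread(D)^2)` independent at every dose point, clipped to
#'   \[0, 100\]. Dosewise errors are exactly Gaussian (the calibration mode),
#'   at the price of curve monotonicity, which is waived and flagged in the
#'   cohort metadata. No noise is added at dose 0, preserving `V(0) = 100`.
#' * `"parametric"` — clinical is itself a valid sigmoid DVH with a shifted
#'   midpoint `d50 + delta_i`, `delta_i ~ N(shiftMean, shiftSD)`; dosewise
#'   errors are approximately Gaussian mid-dose.
#'
#' Defaults emulate a prostate OAR validation cohort: 45 plans, grid
#' 0--110\% Rx in 1\% steps, `d50 ~ N(55, 6)` \% Rx, slope `k = 22` \% Rx
#' (broad enough that predicted volumes stay well inside \[0, 100\] over the
#' 20--90\% interior, keeping clipping negligible there), zero bias and a
#' 3\% volume spread.
#'
#' @slot n plan count.
#' @slot grid the [DoseGrid].
#' @slot d50Mean,d50SD sigmoid midpoint distribution, \% Rx.
#' @slot slopeK sigmoid steepness, \% Rx.
#' @slot biasFn,spreadFn functions dose -> \% volume (injected `mu(D)` and
#'   `sigma(D)`); scalars are promoted to constant functions.
#' @slot mode `"pointwise"` or `"parametric"`.
#' @slot shiftMean,shiftSD midpoint-shift distribution for parametric mode,
#'   \% Rx.
#' @slot seed integer seed; the same seed reproduces the cohort bit for bit
#'   (Mersenne-Twister with inversion normals).
#' @aliases SyntheticSpec-class
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
         representation(n = "integer", grid = "DoseGrid",
                        d50Mean = "numeric", d50SD = "numeric",
                        slopeK = "numeric", biasFn = "function",
                        spreadFn = "function", mode = "character",
                        shiftMean = "numeric", shiftSD = "numeric",
                        seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  msg <- NULL
  if (object@n < 1L) msg <- c(msg, "'n' must be >= 1")
  if (object@d50Mean <= 0) msg <- c(msg, "'d50Mean' must be > 0")
  if (object@d50SD < 0) msg <- c(msg, "'d50SD' must be >= 0")
  if (object@slopeK <= 0) msg <- c(msg, "'slopeK' must be > 0")
  if (!object@mode %in% c("pointwise", "parametric"))
    msg <- c(msg, "'mode' must be 'pointwise' or 'parametric'")
  if (object@shiftSD < 0) msg <- c(msg, "'shiftSD' must be >= 0")
  sp <- object@spreadFn(doseSeq(object@grid))
  if (any(sp < 0)) msg <- c(msg, "spread function must be >= 0 everywhere")
  if (is.null(msg)) TRUE else msg
})

.asDoseFn <- function(x) {
  if (is.function(x)) return(x)
  stopifnot(is.numeric(x), length(x) == 1L)
  force(x)
  function(dose) rep(as.numeric(x), length(dose))
}

#' @param n plan count (default 45, a typical validation-set size).
#' @param grid a [DoseGrid].
#' @param d50Mean,d50SD,slopeK sigmoid shape parameters, \% Rx.
#' @param bias,spread injected dosewise bias and spread: scalars
#'   (\% volume) or functions of dose.
#' @param mode `"pointwise"` (exact Gaussian errors) or `"parametric"`
#'   (valid DVH shapes).
#' @param shiftMean,shiftSD parametric-mode midpoint shift, \% Rx.
#' @param seed integer seed.
#' @return A `SyntheticSpec`.
#' @examples
#' syntheticSpec(n = 10, seed = 7)
#' @rdname SyntheticSpec-class
#' @export
syntheticSpec <- function(n = 45, grid = DoseGrid(), d50Mean = 55, d50SD = 6,
                          slopeK = 22, bias = 0, spread = 3,
                          mode = c("pointwise", "parametric"),
                          shiftMean = 0, shiftSD = 4, seed = 1) {
  new("SyntheticSpec", n = as.integer(n), grid = grid,
      d50Mean = as.numeric(d50Mean), d50SD = as.numeric(d50SD),
      slopeK = as.numeric(slopeK), biasFn = .asDoseFn(bias),
      spreadFn = .asDoseFn(spread), mode = match.arg(mode),
      shiftMean = as.numeric(shiftMean), shiftSD = as.numeric(shiftSD),
      seed = as.integer(seed))
}

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec: n = %d, mode '%s', d50 ~ N(%g, %g), k = %g, seed %d\n",
    object@n, object@mode, object@d50Mean, object@d50SD, object@slopeK,
    object@seed))
})

#' Sigmoid baseline DVH
#'
#' `V(D) = 100 * s(D) / s(0)` with `s(D) = 1 / (1 + exp((D - d50) / k))`:
#' monotone non-increasing, `V(0) = 100` exactly, approaching a step at
#' `d50` as `k -> 0`.
#'
#' @param d50 midpoint dose, \% Rx (`> 0`).
#' @param k steepness, \% Rx (`> 0`).
#' @param grid a [DoseGrid].
#' @param planId,oar labels for the resulting curve.
#' @return A [DVHCurve] on `grid`.
#' @export
baselineDVH <- function(d50, k, grid = DoseGrid(), planId = "plan",
                        oar = "synthetic") {
  if (d50 <= 0 || k <= 0)
    stop("'d50' and 'k' must be positive", call. = FALSE)
  doses <- doseSeq(grid)
  DVHCurve(doses, .sigmoidVolume(doses, d50, k), planId = planId, oar = oar,
           check = FALSE)
}

.sigmoidVolume <- function(dose, d50, k) {
  s <- function(D) stats::plogis(-(D - d50) / k)  # 1 / (1 + exp((D-d50)/k))
  100 * s(dose) / s(0)
}

#' Generate a synthetic DVH cohort with known ground truth
#'
#' Draws per-plan sigmoid predictions and injects prediction errors per the
#' [syntheticSpec()] mode. The injected dosewise truth is stored in
#' `metadata(cohort)$truth` for [truthReport()]; the per-plan `d50` is the
#' cohort feature. Identical seeds reproduce identical cohorts.
#'
#' @param spec a [SyntheticSpec].
#' @return A [DVHCohort] with `metadata()$truth` and `metadata()$spec`.
#' @examples
#' co <- simulateCohort(syntheticSpec(n = 5, seed = 3))
#' co
#' @export
simulateCohort <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  set.seed(spec@seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  doses <- doseSeq(spec@grid)
  nD <- length(doses); n <- spec@n
  d50 <- rnorm(n, spec@d50Mean, spec@d50SD)
  if (any(d50 <= 0)) {
    warning("non-positive d50 draw(s) clamped", call. = FALSE)
    d50 <- pmax(d50, 1e-3)
  }
  pred <- vapply(d50, function(m) .sigmoidVolume(doses, m, spec@slopeK),
                 numeric(nD))
  atZero <- doses == 0
  if (spec@mode == "pointwise") {
    biasVec <- spec@biasFn(doses)
    spreadVec <- spec@spreadFn(doses)
    noise <- matrix(rnorm(nD * n, mean = 0, sd = spreadVec), nrow = nD)
    clin <- pred + biasVec + noise
    clin[atZero, ] <- pred[atZero, ]      # keep V(0) = 100
    clin <- pmin(pmax(clin, 0), 100)
    truth <- list(mode = "pointwise",
                  bias = ifelse(atZero, 0, biasVec),
                  spread = ifelse(atZero, 0, spreadVec))
    waived <- TRUE
  } else {
    delta <- rnorm(n, spec@shiftMean, spec@shiftSD)
    d50c <- pmax(d50 + delta, 1e-3)
    clin <- vapply(d50c, function(m) .sigmoidVolume(doses, m, spec@slopeK),
                   numeric(nD))
    truth <- list(mode = "parametric", shiftMean = spec@shiftMean,
                  shiftSD = spec@shiftSD, delta = delta)
    waived <- FALSE
  }
  cohortFromMatrices(clin, pred, grid = spec@grid, oar = "synthetic",
                     planIds = sprintf("plan%04d", seq_len(n)),
                     feature = d50,
                     metadata = list(truth = truth, spec = spec,
                                     monotone_waived = waived))
}

#' Compare injected against estimated error statistics
#'
#' Joins the generator's ground truth with the cohort's [summarizeErrors()]
#' estimates. In pointwise mode, reports the dosewise injected-vs-estimated
#' bias and spread with their maximum absolute discrepancies over the
#' interior dose range and the corresponding standard errors
#' (`SE(mu) = s / sqrt(n)`, `SE(sigma) ~ s / sqrt(2(n-1))`). In parametric
#' mode, additionally runs a Shapiro-Wilk normality sanity check of the
#' dosewise errors at a few mid-dose points.
#'
#' @param cohort a [DVHCohort] from [simulateCohort()].
#' @param interior dose range (\% Rx) over which discrepancies are assessed;
#'   the default 20--90\% excludes the clipping-prone extremes.
#' @param alpha significance level of the normality check (parametric mode).
#' @param normalityDoses dose points (\% Rx) at which normality is checked.
#' @return A list: `table` (dosewise injected/estimated values), maximum
#'   absolute discrepancies, standard errors, `within3SE` (logical, interior
#'   range), and in parametric mode `normality` (data.frame of p-values) and
#'   `normalityPass`.
#' @export
truthReport <- function(cohort, interior = c(20, 90), alpha = 0.01,
                        normalityDoses = c(40, 55, 70)) {
  stopifnot(is(cohort, "DVHCohort"))
  truth <- metadata(cohort)$truth
  if (is.null(truth))
    stop("cohort carries no ground truth (not from simulateCohort?)",
         call. = FALSE)
  es <- suppressWarnings(summarizeErrors(cohort))
  doses <- doseValues(cohort)
  sel <- doses >= interior[1] & doses <= interior[2]
  n <- nPlans(cohort)
  if (truth$mode == "pointwise") {
    tab <- data.frame(dose_pct = doses,
                      injected_bias = truth$bias, est_mu = errorBias(es),
                      injected_spread = truth$spread, est_sigma = errorSD(es))
    seMu <- truth$spread / sqrt(n)
    seSigma <- truth$spread / sqrt(2 * max(n - 1L, 1L))
    dMu <- abs(tab$est_mu - tab$injected_bias)
    dSigma <- abs(tab$est_sigma - tab$injected_spread)
    list(table = tab,
         max_abs_mu_discrepancy = max(dMu[sel]),
         max_abs_sigma_discrepancy = if (n >= 2L) max(dSigma[sel]) else NA,
         se_mu = seMu, se_sigma = seSigma,
         within3SE = n >= 2L &&
           all(dMu[sel] <= 3 * seMu[sel]) &&
           all(dSigma[sel] <= 3 * seSigma[sel]),
         interior = interior)
  } else {
    err <- dosewiseErrors(cohort)
    idx <- vapply(normalityDoses, function(d) which.min(abs(doses - d)),
                  integer(1))
    pv <- vapply(idx, function(i) {
      e <- err[i, ]
      if (sd(e) == 0) return(NA_real_)
      shapiro.test(e)$p.value
    }, numeric(1))
    norm <- data.frame(dose_pct = doses[idx], shapiro_p = pv)
    tab <- data.frame(dose_pct = doses, est_mu = errorBias(es),
                      est_sigma = errorSD(es))
    list(table = tab, normality = norm,
         normalityPass = all(is.na(pv) | pv >= alpha),
         alpha = alpha, interior = interior)
  }
}
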