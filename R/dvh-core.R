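## DVH validation, grid resampling and long-format tabular I/O.

#' Validate cumulative-DVH semantics
#'
#' Checks that a curve behaves like a cumulative DVH: volumes within
#' \[0, 100\] \% of OAR volume, non-increasing along the dose axis, and
#' `V(0) = 100` (within `tolerance`) when dose 0 is tabulated.
#'
#' @param x a [DVHCurve], or a numeric dose vector (with `volume` supplied).
#' @param volume numeric volume vector when `x` is a dose vector.
#' @param tolerance allowed deviation of `V(0)` from 100, \% OAR volume.
#' @return A list with elements `pass` (logical) and `violations`
#'   (character vector, empty when the curve passes).
#' @examples
#' validateDVH(c(0, 50, 110), c(100, 60, 0))$pass
#' validateDVH(c(0, 50, 60), c(100, 60, 65))$violations
#' @export
validateDVH <- function(x, volume = NULL, tolerance = 1e-6) {
  if (is(x, "DVHCurve")) {
    dose <- x@dose; volume <- x@volume
  } else {
    dose <- as.numeric(x); volume <- as.numeric(volume)
  }
  if (length(dose) < 2L || length(volume) < 2L)
    stop("a DVH curve needs at least 2 points", call. = FALSE)
  if (length(dose) != length(volume))
    stop("dose and volume lengths differ", call. = FALSE)
  viol <- character(0)
  bad <- which(volume < -tolerance | volume > 100 + tolerance)
  if (length(bad))
    viol <- c(viol, sprintf("volume out of [0, 100] at dose %g (V = %g)",
                            dose[bad[1L]], volume[bad[1L]]))
  up <- which(diff(volume) > tolerance)
  if (length(up))
    viol <- c(viol, sprintf("non-monotone segment: volume increases at dose %g",
                            dose[up[1L] + 1L]))
  iz <- which(dose == 0)
  if (length(iz) && abs(volume[iz[1L]] - 100) > tolerance)
    viol <- c(viol, sprintf("V(0) = %g differs from 100", volume[iz[1L]]))
  list(pass = length(viol) == 0L, violations = viol)
}

#' Resample a DVH curve onto a dose grid
#'
#' Linear interpolation between tabulated points. Grid doses beyond the
#' curve's maximum tabulated dose map to volume 0; doses below its minimum
#' map to 100. A curve already tabulated on the grid is returned unchanged
#' (idempotence), and monotone input yields monotone output.
#'
#' @param curve a [DVHCurve].
#' @param grid a [DoseGrid].
#' @return A [DVHCurve] on `grid`.
#' @examples
#' cv <- DVHCurve(c(0, 100), c(100, 0))
#' resampleToGrid(cv, DoseGrid(0, 110, 25))
#' @export
resampleToGrid <- function(curve, grid) {
  stopifnot(is(curve, "DVHCurve"), is(grid, "DoseGrid"))
  doses <- doseSeq(grid)
  vol <- approx(curve@dose, curve@volume, xout = doses,
                yleft = 100, yright = 0, ties = "ordered")$y
  DVHCurve(doses, vol, planId = curve@planId, oar = curve@oar, check = FALSE)
}

## long-format dialect shared by readCohort/writeCohort
.roles <- c("clinical", "predicted", "band_lower", "band_upper")
.cohortKey <- "__cohort__"

#' Read a DVH cohort from a long-format table
#'
#' Consumes the package's long-format CSV dialect: header
#' `plan_id,oar,role,dose_pct,volume_pct` with
#' `role` one of `clinical`, `predicted`, `band_lower`, `band_upper`.
#' Rows are grouped into curves, each curve is validated and resampled onto
#' `grid`, clinical/predicted curves are paired by plan id, and model-provided
#' band curves (when present) are attached — per plan, or cohort-level under
#' the reserved plan id `"__cohort__"`.
#'
#' Duplicate doses within one curve keep the last row (with a warning).
#' `renormalize = TRUE` rescales each curve so its volume at the lowest
#' tabulated dose is exactly 100 before validation.
#'
#' @param file path to a CSV file, or a data.frame in the same layout.
#' @param grid target [DoseGrid].
#' @param oar which OAR to load when the table holds several; mandatory in
#'   that case.
#' @param renormalize rescale curves to `V(0) = 100` before validating.
#' @param strict fail on curves violating cumulative-DVH semantics (default);
#'   with `strict = FALSE` offenders are listed in a warning and kept, which
#'   permits round-tripping deliberately non-monotone simulated cohorts.
#' @return A [DVHCohort]; a cohort-level model band, if present, is stored in
#'   `metadata()$model_band`.
#' @seealso [writeCohort()] for the inverse operation.
#' @export
readCohort <- function(file, grid = DoseGrid(), oar = NULL,
                       renormalize = FALSE, strict = TRUE) {
  tab <- if (is.data.frame(file)) file else
    read.csv(file, stringsAsFactors = FALSE)
  need <- c("plan_id", "oar", "role", "dose_pct", "volume_pct")
  if (!all(need %in% names(tab)))
    stop("table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(tab$role %in% .roles))
    stop("unknown role(s): ",
         paste(setdiff(unique(tab$role), .roles), collapse = ", "),
         call. = FALSE)
  oars <- unique(tab$oar)
  if (is.null(oar)) {
    if (length(oars) > 1L)
      stop("table holds several OARs (", paste(oars, collapse = ", "),
           "); pass 'oar' to select one", call. = FALSE)
    oar <- oars
  }
  tab <- tab[tab$oar == oar, , drop = FALSE]
  if (!nrow(tab)) stop("no rows for OAR '", oar, "'", call. = FALSE)

  mkCurve <- function(df, pid) {
    df <- df[order(df$dose_pct), , drop = FALSE]
    dup <- duplicated(df$dose_pct, fromLast = TRUE)
    if (any(dup)) {
      warning("plan '", pid, "': duplicate dose values, keeping last",
              call. = FALSE)
      df <- df[!dup, , drop = FALSE]
    }
    v <- df$volume_pct
    if (renormalize && v[1L] > 0) v <- v * 100 / v[1L]
    DVHCurve(df$dose_pct, v, planId = pid, oar = oar, check = FALSE)
  }
  curvesByRole <- function(role) {
    sub <- tab[tab$role == role, , drop = FALSE]
    if (!nrow(sub)) return(list())
    lapply(split(sub, sub$plan_id)[unique(sub$plan_id)], function(df)
      mkCurve(df, df$plan_id[1L]))
  }
  clin <- curvesByRole("clinical")
  pred <- curvesByRole("predicted")
  if (!length(clin) || !length(pred))
    stop("table needs both clinical and predicted curves", call. = FALSE)

  ## validate each curve, reporting offenders by plan id
  failures <- character(0)
  for (role in c("clinical", "predicted")) {
    for (cv in (if (role == "clinical") clin else pred)) {
      rep <- validateDVH(cv)
      if (!rep$pass)
        failures <- c(failures,
                      sprintf("%s [%s]: %s", cv@planId, role,
                              paste(rep$violations, collapse = "; ")))
    }
  }
  if (length(failures)) {
    msg <- paste0("invalid DVH curve(s):\n  ",
                  paste(failures, collapse = "\n  "))
    if (strict) stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
    clipCurve <- function(cv) {
      cv@volume <- pmin(pmax(cv@volume, 0), 100)
      cv
    }
    clin <- lapply(clin, clipCurve)
    pred <- lapply(pred, clipCurve)
  }

  bl <- curvesByRole("band_lower"); bu <- curvesByRole("band_upper")
  cohortBand <- NULL
  pidOf <- function(xs) vapply(xs, function(c) c@planId, character(1))
  if (length(bl) || length(bu)) {
    if (.cohortKey %in% c(pidOf(bl), pidOf(bu))) {
      if (!all(.cohortKey %in% pidOf(bl)) || !all(.cohortKey %in% pidOf(bu)))
        stop("cohort-level band needs both lower and upper curves",
             call. = FALSE)
      lo <- resampleToGrid(bl[[.cohortKey]], grid)@volume
      hi <- resampleToGrid(bu[[.cohortKey]], grid)@volume
      cohortBand <- .makeBand("model_provided", doseSeq(grid),
                              cbind(lo), cbind(hi), scope = "cohort")
      bl <- bl[pidOf(bl) != .cohortKey]; bu <- bu[pidOf(bu) != .cohortKey]
    }
  }
  co <- DVHCohort(clinical = unname(clin), predicted = unname(pred),
                  grid = grid, oar = oar,
                  bandLower = if (length(bl)) unname(bl) else NULL,
                  bandUpper = if (length(bu)) unname(bu) else NULL)
  if (!is.null(cohortBand)) metadata(co)$model_band <- cohortBand
  co
}

#' Write a DVH cohort as a long-format table
#'
#' Emits the same dialect [readCohort()] consumes; reading the result back
#' reproduces the cohort up to row order and serialized float precision.
#'
#' @param cohort a [DVHCohort].
#' @param file path to write a CSV to, or `NULL` to return the data.frame.
#' @return The long-format data.frame, invisibly when `file` is given.
#' @export
writeCohort <- function(cohort, file = NULL) {
  stopifnot(is(cohort, "DVHCohort"))
  doses <- doseValues(cohort)
  oneRole <- function(mat, role) {
    do.call(rbind, lapply(colnames(mat), function(pid)
      data.frame(plan_id = pid, oar = oarLabel(cohort), role = role,
                 dose_pct = doses, volume_pct = mat[, pid])))
  }
  out <- rbind(oneRole(clinicalVolumes(cohort), "clinical"),
               oneRole(predictedVolumes(cohort), "predicted"))
  if (all(c("band_lower", "band_upper") %in% assayNames(cohort)))
    out <- rbind(out,
                 oneRole(assay(cohort, "band_lower"), "band_lower"),
                 oneRole(assay(cohort, "band_upper"), "band_upper"))
  mb <- metadata(cohort)$model_band
  if (!is.null(mb) && bandScope(mb) == "cohort") {
    cb <- function(v, role)
      data.frame(plan_id = .cohortKey, oar = oarLabel(cohort), role = role,
                 dose_pct = doses, volume_pct = as.numeric(v))
    out <- rbind(out, cb(bandLower(mb), "band_lower"),
                 cb(bandUpper(mb), "band_upper"))
  }
  rownames(out) <- NULL
  if (is.null(file)) return(out)
  write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' Export a cohort (or its curves) as JSON
#'
#' Mirrors the long-format fields for report embedding.
#'
#' @param cohort a [DVHCohort].
#' @param file path to write to, or `NULL` to return the JSON string.
#' @return JSON string, invisibly when `file` is given.
#' @export
cohortToJSON <- function(cohort, file = NULL) {
  payload <- list(oar = oarLabel(cohort),
                  dose_pct = doseValues(cohort),
                  plans = lapply(planIds(cohort), function(pid) list(
                    plan_id = pid,
                    clinical = unname(clinicalVolumes(cohort)[, pid]),
                    predicted = unname(predictedVolumes(cohort)[, pid]))))
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (is.null(file)) return(js)
  writeLines(js, file)
  invisible(js)
}
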