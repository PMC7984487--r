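# Fixture builders shared across the test files. All fixtures are built in
# code; nothing is read from disk except explicit round-trip temp files.

# cohort on a small grid from dose-by-plan matrices (values % OAR volume)
toyCohort <- function(clinical, predicted, grid = DoseGrid(0, 10, 5),
                      feature = NULL) {
  cohortFromMatrices(clinical, predicted, grid = grid, oar = "toy",
                     feature = feature)
}

# cohort whose every dose row repeats the same clinical values across plans
flatCohort <- function(values, predicted = NULL, grid = DoseGrid(0, 10, 5),
                       feature = NULL) {
  nD <- length(doseSeq(grid))
  clin <- matrix(rep(values, each = nD), nrow = nD)
  if (is.null(predicted)) predicted <- matrix(mean(values), nD, length(values))
  toyCohort(clin, predicted, grid = grid, feature = feature)
}

# random valid (monotone) DVH curve for property-style loops
randomCurve <- function(id = "p", npts = 6) {
  doses <- sort(c(0, runif(npts - 2, 1, 109), 110))
  vols <- c(100, sort(runif(npts - 2, 0, 100), decreasing = TRUE), 0)
  vols <- cummin(vols)[seq_along(doses)]
  DVHCurve(doses, vols[seq_along(doses)], planId = id, oar = "toy")
}

# paired random cohort of valid curves
randomCohort <- function(n = 4, grid = DoseGrid(0, 110, 10)) {
  mk <- function(role) lapply(seq_len(n), function(i)
    randomCurve(sprintf("p%02d", i)))
  DVHCohort(mk("clin"), mk("pred"), grid = grid, oar = "toy")
}
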