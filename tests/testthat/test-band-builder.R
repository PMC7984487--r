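test_that("RMSE band is the prediction +/- RMSE, clipped to [0, 100]", {
  # predictions at 50 across 3 dose points; errors +3/-3 with zero mean give
  # RMSE = 3 at every dose, so the band is [47, 53]
  pred <- matrix(50, 3, 4)
  clin <- pred + matrix(c(3, -3, 3, -3), 3, 4, byrow = TRUE)
  co <- toyCohort(clin, pred)
  es <- summarizeErrors(co)
  b <- rmseBand(co, es)
  expect_equal(bandKind(b), "rmse")
  expect_equal(bandScope(b), "plan")
  expect_equal(unname(bandLower(b)[1, ]), rep(47, 4))
  expect_equal(unname(bandUpper(b)[1, ]), rep(53, 4))

  # prediction 1 with the same RMSE 3 clips at zero: [0, 4]
  coLow <- toyCohort(matrix(1, 3, 4), matrix(1, 3, 4))
  bLow <- rmseBand(coLow, es)
  expect_equal(unname(bandLower(bLow)[1, 1]), 0)
  expect_equal(unname(bandUpper(bLow)[1, 1]), 4)

  # zero RMSE collapses the band onto the prediction
  ident <- toyCohort(pred, pred)
  b0 <- rmseBand(ident)
  expect_equal(bandLower(b0), predictedVolumes(ident))
  expect_equal(bandUpper(b0), predictedVolumes(ident))
})

test_that("IQR band uses linear percentile interpolation", {
  co <- flatCohort(c(1, 2, 3, 4))
  b <- iqrBand(co)
  # hand oracle for {1,2,3,4}: Q1 at rank 1.75 -> 1.75, Q3 at 3.25 -> 3.25
  expect_equal(unique(as.numeric(bandLower(b))), 1.75)
  expect_equal(unique(as.numeric(bandUpper(b))), 3.25)
  expect_equal(bandScope(b), "cohort")

  same <- flatCohort(rep(42, 5))
  bz <- iqrBand(same)
  expect_true(all(bandUpper(bz) - bandLower(bz) == 0))

  expect_error(iqrBand(flatCohort(1)), "single-plan")
})

test_that("IQR half-width approaches the normal quartile 0.674 sigma", {
  set.seed(123)
  x <- pmin(pmax(rnorm(1e5, mean = 50, sd = 1), 0), 100)
  co <- flatCohort(x, grid = DoseGrid(0, 10, 10))
  b <- iqrBand(co)
  halfWidth <- (bandUpper(b)[1, 1] - bandLower(b)[1, 1]) / 2
  expect_equal(halfWidth, qnorm(0.75), tolerance = 0.02)
})

test_that("median-split band averages the two feature halves", {
  co <- flatCohort(c(10, 20, 30, 40), feature = c(1, 2, 3, 4))
  b <- medianSplitBand(co)
  # features {1,2} vs {3,4}: half means 15 and 35 by hand
  expect_equal(unique(as.numeric(bandLower(b))), 15)
  expect_equal(unique(as.numeric(bandUpper(b))), 35)

  # odd n: the median plan joins both halves -> {10,20} and {20,30}
  co3 <- flatCohort(c(10, 20, 30), feature = c(1, 2, 3))
  b3 <- medianSplitBand(co3)
  expect_equal(unique(as.numeric(bandLower(b3))), 15)
  expect_equal(unique(as.numeric(bandUpper(b3))), 25)

  # uncorrelated feature, identical values: zero width
  bz <- medianSplitBand(flatCohort(rep(7, 4), feature = c(4, 3, 2, 1)))
  expect_true(all(bandUpper(bz) == bandLower(bz)))

  expect_warning(medianSplitBand(flatCohort(c(1, 2, 3, 4),
                                            feature = rep(1, 4))),
                 "degenerate")
  expect_error(medianSplitBand(flatCohort(c(1, 2))), "feature")
})

test_that("self-matching median split tends to the half-normal mean width", {
  set.seed(31)
  x <- rnorm(1e5, mean = 50, sd = 3)
  co <- flatCohort(pmin(pmax(x, 0), 100), grid = DoseGrid(0, 10, 10))
  b <- medianSplitBand(co, pointwise = TRUE)
  halfWidth <- (bandUpper(b)[1, 1] - bandLower(b)[1, 1]) / 2
  expect_equal(halfWidth, 3 * sqrt(2 / pi), tolerance = 0.02)
})

test_that("model-provided bands are validated and symmetry-flagged", {
  pred <- matrix(50, 3, 2)
  bSym <- modelBand(lower = pred - 2, upper = pred + 2, predicted = pred,
                    dose = c(0, 5, 10))
  expect_true(bSym@symmetric)
  bAsym <- modelBand(lower = pred - 1, upper = pred + 2, predicted = pred,
                     dose = c(0, 5, 10))
  expect_false(bAsym@symmetric)

  lo <- pred - 2; lo[2, 1] <- 55   # lower bound crosses above at dose 5
  expect_error(modelBand(lower = lo, upper = pred + 2, predicted = pred,
                         dose = c(0, 5, 10)),
               "band-integrity.*5")
})

test_that("model band from file equals direct construction", {
  g <- DoseGrid(0, 110, 55)
  d <- doseSeq(g)
  mk <- function(v, id) DVHCurve(d, v, planId = id, check = FALSE)
  tab <- rbind(
    data.frame(plan_id = "p1", oar = "x", role = "clinical", dose_pct = d,
               volume_pct = c(100, 50, 0)),
    data.frame(plan_id = "p1", oar = "x", role = "predicted", dose_pct = d,
               volume_pct = c(100, 48, 0)),
    data.frame(plan_id = "p1", oar = "x", role = "band_lower", dose_pct = d,
               volume_pct = c(95, 43, 0)),
    data.frame(plan_id = "p1", oar = "x", role = "band_upper", dose_pct = d,
               volume_pct = c(100, 53, 5)))
  co <- readCohort(tab, grid = g)
  bFile <- modelBand(co)
  bDirect <- modelBand(lower = cbind(c(95, 43, 0)),
                       upper = cbind(c(100, 53, 5)),
                       predicted = predictedVolumes(co), dose = d)
  expect_equal(bandLower(bFile), bandLower(bDirect), ignore_attr = TRUE)
  expect_equal(bandUpper(bFile), bandUpper(bDirect), ignore_attr = TRUE)
  expect_equal(bandKind(bFile), "model_provided")
})

test_that("every produced band satisfies the bound invariants", {
  set.seed(77)
  for (i in 1:10) {
    co <- randomCohort(n = 5)
    bands <- list(rmseBand(co), iqrBand(co),
                  medianSplitBand(co, feature = runif(5)))
    for (b in bands) {
      expect_true(all(bandLower(b) <= bandUpper(b) + 1e-9))
      expect_true(all(bandLower(b) >= 0 & bandUpper(b) <= 100))
    }
  }
})
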