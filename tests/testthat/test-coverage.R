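test_that("the tally rule combines band membership with the volume tolerance", {
  expect_true(pointWithinBand(50, 50, 47, 53))
  # outside the band but < 0.5% volume from the prediction: still a success
  expect_true(pointWithinBand(50.4, 50, 49.8, 50.2))
  expect_false(pointWithinBand(51.0, 50, 49.8, 50.2))
  # the comparison is strict: exactly at tolerance is a failure
  expect_false(pointWithinBand(50.5, 50, 49.8, 50.2, tolerance = 0.5))
  # distance is measured to the prediction, not the nearer band edge
  expect_false(pointWithinBand(50.6, 50, 50.1, 50.2, tolerance = 0.5))
  expect_error(pointWithinBand(50, 50, 53, 47), "band-integrity")
})

test_that("coverage counts successes per dose point across plans", {
  # 4 plans; at dose index 2 exactly two clinical values are inside [40, 60]
  clin <- rbind(c(50, 50, 50, 50),
                c(45, 55, 70, 20),
                c(50, 50, 50, 50))
  pred <- matrix(50, 3, 4)
  co <- toyCohort(clin, pred)
  b <- modelBand(lower = matrix(40, 3, 4), upper = matrix(60, 3, 4),
                 predicted = pred, dose = doseValues(co))
  cc <- coverageCurve(co, b, tolerance = 0, window = 1)
  expect_equal(rawCoverage(cc), c(1, 0.5, 1))
  expect_equal(rawCoverage(cc) * nPlans(co), round(rawCoverage(cc) * 4))

  # everything inside its band everywhere
  ccAll <- coverageCurve(co, widenBand(b, 50), tolerance = 0, window = 1)
  expect_true(all(rawCoverage(ccAll) == 1))
})

test_that("boxcar smoothing is a centered mean with shrinking edges", {
  expect_equal(boxcarSmooth(rep(0.4, 15), 11), rep(0.4, 15))
  expect_equal(boxcarSmooth(1:7, 1), as.numeric(1:7))

  # unit impulse centered in 21 zeros: eleven consecutive values of 1/11
  x <- rep(0, 21); x[11] <- 1
  sm <- boxcarSmooth(x, 11)
  expect_equal(sm[6:16], rep(1 / 11, 11))
  expect_equal(sm[c(1:5, 17:21)], rep(0, 10))

  # symmetric shrinking at the edges, by hand: window 3 over c(0,0,6,0,0)
  expect_equal(boxcarSmooth(c(0, 0, 6, 0, 0), 3), c(0, 2, 2, 2, 0))

  expect_error(boxcarSmooth(1:10, 4), "odd")
  expect_error(boxcarSmooth(1:5, 7), "length")
})

test_that("smoothing never leaves the raw range", {
  set.seed(5)
  for (i in 1:10) {
    x <- runif(30)
    sm <- boxcarSmooth(x, 11)
    expect_true(all(sm >= min(x) - 1e-12 & sm <= max(x) + 1e-12))
  }
})

test_that("coverage summaries read off the curve in percent", {
  co <- toyCohort(matrix(50, 3, 5), matrix(50, 3, 5))
  b <- rmseBand(co)
  cc <- coverageCurve(co, b, tolerance = 0.5, window = 1)
  s <- coverageSummary(cc)
  expect_equal(s$min, 100); expect_equal(s$mean, 100)

  # toy raw curve {0.4, 0.5, 0.6}: min 40%, max 60%
  cc2 <- new("CoverageCurve", dose = c(0, 5, 10), raw = c(0.4, 0.5, 0.6),
             smoothed = c(0.4, 0.5, 0.6), window = 1L, tolerance = 0,
             n = 10L, kind = "rmse")
  s2 <- coverageSummary(cc2, use = "raw")
  expect_equal(c(s2$min, s2$max), c(40, 60))

  # restricting the range can never widen [min, max]
  sub <- coverageSummary(cc2, range = c(0, 5), use = "raw")
  expect_gte(sub$min, s2$min)
  expect_lte(sub$max, s2$max)
  expect_error(coverageSummary(cc2, range = c(20, 30)), "empty")
})

test_that("coverage is monotone in tolerance and in band width", {
  set.seed(8)
  for (i in 1:5) {
    co <- randomCohort(n = 6)
    b <- iqrBand(co)
    cov0 <- rawCoverage(coverageCurve(co, b, tolerance = 0, window = 1))
    cov1 <- rawCoverage(coverageCurve(co, b, tolerance = 1, window = 1))
    cov5 <- rawCoverage(coverageCurve(co, b, tolerance = 5, window = 1))
    expect_true(all(cov1 >= cov0) && all(cov5 >= cov1))

    wide <- rawCoverage(coverageCurve(co, widenBand(b, 3), tolerance = 0,
                                      window = 1))
    expect_true(all(wide >= cov0))
  }
})

test_that("per-plan bands must cover every plan", {
  co <- toyCohort(matrix(50, 3, 3), matrix(50, 3, 3))
  b <- rmseBand(co)
  b@planIds <- c("plan01", "plan02", "zzz")
  b@lower <- b@lower[, 1:3]; b@upper <- b@upper[, 1:3]
  expect_error(coverageCurve(co, b), "pairing error.*plan03")
})
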