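test_that("validateDVH enforces cumulative-DVH semantics", {
  expect_true(validateDVH(c(0, 50, 110), c(100, 60, 0))$pass)

  rep <- validateDVH(c(0, 50, 60), c(100, 60, 65))
  expect_false(rep$pass)
  expect_match(rep$violations, "non-monotone.*60", all = FALSE)

  rep <- validateDVH(c(0, 110), c(98, 0))
  expect_false(rep$pass)
  expect_match(rep$violations, "V\\(0\\)", all = FALSE)

  expect_error(validateDVH(0, 100), "at least 2 points")
  expect_error(DVHCurve(c(0, 50, 60), c(100, 60, 65)), "non-monotone")
})

test_that("resampling interpolates linearly with the boundary rules", {
  cv <- DVHCurve(c(0, 100), c(100, 0))
  rs <- resampleToGrid(cv, DoseGrid(0, 110, 25))
  # hand-computed: straight line 100 -> 0 over 0..100, zero beyond
  expect_equal(rs@volume, c(100, 75, 50, 25, 0))

  cv2 <- DVHCurve(c(0, 80), c(100, 10))
  rs2 <- resampleToGrid(cv2, DoseGrid(0, 110, 10))
  # at 40: halfway along the segment -> (100 + 10) / 2 = 55 by hand
  expect_equal(rs2@volume[rs2@dose == 40], 55)
  expect_equal(rs2@volume[rs2@dose > 80], c(0, 0, 0))
})

test_that("resampling is idempotent and preserves monotonicity", {
  g <- DoseGrid(0, 110, 10)
  onGrid <- DVHCurve(doseSeq(g), seq(100, 0, length.out = 12))
  expect_identical(resampleToGrid(onGrid, g)@volume, onGrid@volume)

  set.seed(42)
  for (i in 1:20) {
    cv <- randomCurve()
    rs <- resampleToGrid(cv, DoseGrid(0, 110, 3))
    expect_true(all(diff(rs@volume) <= 1e-9))
    expect_true(all(rs@volume >= 0 & rs@volume <= 100))
    expect_equal(rs@volume[1], 100)
  }
})

test_that("cohort construction pairs plans and rejects mismatches", {
  g <- DoseGrid(0, 110, 10)
  mk <- function(id) DVHCurve(c(0, 60, 110), c(100, 50, 0), planId = id)
  co <- DVHCohort(list(mk("a"), mk("b")), list(mk("a"), mk("b")), grid = g)
  expect_s4_class(co, "DVHCohort")
  expect_equal(nPlans(co), 2L)
  expect_setequal(planIds(co), c("a", "b"))

  expect_error(DVHCohort(list(mk("a"), mk("b")), list(mk("a")), grid = g),
               "pairing error.*b")
})

test_that("read/write round-trips the long-format table", {
  g <- DoseGrid(0, 110, 10)
  set.seed(7)
  co <- randomCohort(n = 3, grid = g)
  f <- withr::local_tempfile(fileext = ".csv")
  writeCohort(co, f)
  co2 <- readCohort(f, grid = g)
  expect_equal(clinicalVolumes(co2), clinicalVolumes(co))
  expect_equal(predictedVolumes(co2), predictedVolumes(co))
  expect_setequal(planIds(co2), planIds(co))

  # table round-trip up to row order
  tab <- writeCohort(co2)
  tab0 <- writeCohort(co)
  key <- function(t) t[order(t$plan_id, t$role, t$dose_pct), ]
  expect_equal(key(tab)$volume_pct, key(tab0)$volume_pct)
})

test_that("reader reports validation and pairing failures by plan id", {
  tab <- data.frame(
    plan_id = rep(c("p1", "p1", "p2"), each = 3),
    oar = "rectum",
    role = rep(c("clinical", "predicted", "clinical"), each = 3),
    dose_pct = rep(c(0, 50, 110), 3),
    volume_pct = c(100, 60, 0, 100, 55, 0, 100, 40, 0))
  expect_error(readCohort(tab), "pairing error.*p2")

  bad <- tab[tab$plan_id == "p1", ]
  bad$volume_pct[2] <- 105
  expect_error(readCohort(bad), "p1 \\[clinical\\]")
  # lenient mode downgrades validation failures to a warning and keeps data
  expect_warning(co <- readCohort(bad, strict = FALSE,
                                  grid = DoseGrid(0, 110, 55)),
                 "p1 \\[clinical\\]")
  expect_equal(nPlans(co), 1L)
})

test_that("duplicate doses keep the last row with a warning", {
  tab <- data.frame(plan_id = "p1", oar = "x",
                    role = rep(c("clinical", "predicted"), each = 3),
                    dose_pct = c(0, 50, 50, 0, 50, 110),
                    volume_pct = c(100, 70, 60, 100, 55, 0))
  tab <- rbind(tab, data.frame(plan_id = "p1", oar = "x", role = "clinical",
                               dose_pct = 110, volume_pct = 0))
  expect_warning(co <- readCohort(tab, grid = DoseGrid(0, 110, 50)),
                 "duplicate dose")
  expect_equal(unname(clinicalVolumes(co)[2, 1]), 60)  # last of the two dose-50 rows
})

test_that("renormalization rescales curves to V(0) = 100", {
  tab <- data.frame(plan_id = "p1", oar = "x",
                    role = rep(c("clinical", "predicted"), each = 2),
                    dose_pct = c(0, 110, 0, 110),
                    volume_pct = c(98, 0, 100, 0))
  expect_error(readCohort(tab), "V\\(0\\)")
  co <- readCohort(tab, renormalize = TRUE, grid = DoseGrid(0, 110, 55))
  expect_equal(unname(clinicalVolumes(co)[1, 1]), 100)
})

test_that("JSON export mirrors the cohort fields", {
  set.seed(11)
  co <- randomCohort(n = 2)
  js <- jsonlite::fromJSON(cohortToJSON(co), simplifyVector = TRUE)
  expect_equal(js$oar, "toy")
  expect_equal(js$plans$plan_id, planIds(co))
  expect_equal(js$plans$clinical[[1]], unname(clinicalVolumes(co)[, 1]))
})
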