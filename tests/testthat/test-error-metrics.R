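test_that("error summary reproduces the hand-computed worked example", {
  # errors {1, -1, 2} at one dose point, n = 3; all values by direct
  # arithmetic: mu = 2/3, mean square = 2, sample var = 7/3, pop var = 14/9
  es <- summarizeErrors(matrix(c(1, -1, 2), nrow = 1))
  expect_equal(errorBias(es), 2 / 3)
  expect_equal(errorRMSE(es), sqrt(2))
  expect_equal(errorSD(es), sqrt(7 / 3))
  expect_equal(errorSDPop(es), sqrt(14 / 9))
  expect_equal(round(c(errorBias(es), errorRMSE(es), errorSD(es),
                       errorSDPop(es)), 4),
               c(0.6667, 1.4142, 1.5275, 1.2472))
  # RMSE^2 = mu^2 + sigma_pop^2: 2 = 0.4444 + 1.5556
  expect_equal(errorRMSE(es)^2, errorBias(es)^2 + errorSDPop(es)^2)
})

test_that("errors follow the clinical-minus-predicted sign convention", {
  co <- toyCohort(clinical = matrix(c(60, 55, 30), 3, 2),
                  predicted = matrix(c(58, 58, 30), 3, 2))
  e <- dosewiseErrors(co)
  expect_equal(unname(e[1, 1]), 2)    # clinical above prediction: underprediction
  expect_equal(unname(e[2, 1]), -3)   # clinical below prediction: overprediction
  expect_equal(e[3, ], c(plan01 = 0, plan02 = 0))

  ident <- toyCohort(matrix(50, 3, 2), matrix(50, 3, 2))
  expect_true(all(dosewiseErrors(ident) == 0))
})

test_that("zero and mean-zero error limits behave as expected", {
  es0 <- summarizeErrors(matrix(0, 2, 4))
  expect_true(all(errorBias(es0) == 0 & errorSD(es0) == 0 &
                    errorRMSE(es0) == 0))

  e <- matrix(c(-2, -1, 1, 2), nrow = 1)  # mean exactly zero
  es <- summarizeErrors(e)
  expect_equal(errorBias(es), 0)
  expect_equal(errorRMSE(es), errorSDPop(es))
})

test_that("RMSE is invariant under plan permutation and shifts move only mu", {
  set.seed(3)
  e <- matrix(rnorm(5 * 8, sd = 2), nrow = 5)
  es <- summarizeErrors(e)
  esPerm <- summarizeErrors(e[, sample(8)])
  expect_equal(errorRMSE(esPerm), errorRMSE(es))
  expect_equal(errorSD(esPerm), errorSD(es))

  cshift <- 1.7
  esShift <- summarizeErrors(e + cshift)
  expect_equal(errorBias(esShift), errorBias(es) + cshift)
  expect_equal(errorSD(esShift), errorSD(es))
  # RMSE moves consistently with the quadrature identity
  expect_equal(errorRMSE(esShift)^2,
               errorBias(esShift)^2 + errorSDPop(esShift)^2)
})

test_that("quadrature identity is exact with the population SD", {
  set.seed(9)
  for (n in c(2, 3, 10, 45)) {
    e <- matrix(rnorm(4 * n, mean = runif(1, -2, 2), sd = runif(1, 0.1, 5)),
                nrow = 4)
    qc <- quadratureCheck(summarizeErrors(e))
    expect_lt(qc$max_pop_residual_rel, 1e-9)
    expect_lte(qc$max_sample_residual, qc$sample_bound + 1e-9)
    expect_true(qc$pass)
  }
})

test_that("sample-SD residual equals sigma^2 / n (the 'approximately' in the identity)", {
  es <- summarizeErrors(matrix(c(1, -1, 2), nrow = 1))
  qc <- quadratureCheck(es)
  # hand arithmetic: rmse^2 = 2, mu^2 + sigma^2 = 4/9 + 21/9 = 25/9
  expect_equal(qc$max_sample_residual, 25 / 9 - 2)
  expect_equal(qc$max_sample_residual, errorSD(es)^2 / 3)

  # residual vanishes as the cohort grows
  set.seed(4)
  big <- quadratureCheck(summarizeErrors(matrix(rnorm(2000), nrow = 1)))
  expect_lt(big$max_sample_residual, 0.01)
})

test_that("single-plan cohorts flag sigma as undefined", {
  expect_warning(es <- summarizeErrors(matrix(c(3, 1), ncol = 1)),
                 "sigma is undefined")
  expect_true(all(is.na(errorSD(es))))
  expect_equal(errorSDPop(es), c(0, 0))
  expect_equal(errorBias(es), c(3, 1))
  expect_equal(errorRMSE(es), c(3, 1))
  expect_error(quadratureCheck(es), "n >= 2")
})

test_that("empty input is a structural error", {
  expect_error(summarizeErrors(matrix(numeric(0), nrow = 0)), "empty")
})
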