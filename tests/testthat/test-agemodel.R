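test_that("a noise-free cubic is recovered to numerical precision", {
  co <- c(c0 = 60, c1 = 30, c2 = -2, c3 = 0.1)
  age <- c(0.5, 1, 2, 3.5, 5, 7, 9, 12)
  pairs <- data.frame(age_years = age,
                      femur_length_mm = co[1] + co[2] * age + co[3] * age^2 +
                        co[4] * age^3)
  fit <- fitGrowthCurve(pairs)
  expect_equal(unname(growthCoefficients(fit)), unname(co), tolerance = 1e-6)
  expect_true(fit@monotone)
  ## duplicating every observation leaves the OLS fit unchanged
  fit2 <- fitGrowthCurve(rbind(pairs, pairs))
  expect_equal(growthCoefficients(fit2), growthCoefficients(fit),
               tolerance = 1e-9)
})

test_that("age estimation inverts the curve exactly on synthetic data", {
  ages <- seq(0.2, 12.5, length.out = 20)
  fit <- fitGrowthCurve(data.frame(
    age_years = ages,
    femur_length_mm = predictLength(defaultGrowthCurve(), ages)))
  for (a in c(0.5, 2, 6.3, 11)) {
    fl <- predictLength(fit, a)
    expect_equal(estimateAge(fit, fl), a, tolerance = 1e-6)
  }
})

test_that("reference-sample growth curve reproduces the printed age estimates", {
  curve <- fitGrowthCurve(growthCalibrationPairs())
  expect_true(curve@monotone)
  expect_equal(round(estimateAge(curve, 163.1), 2), 3.99, tolerance = 0.25)
  expect_equal(round(estimateAge(curve, 239.7), 2), 11.26, tolerance = 0.25)
})

test_that("extrapolation beyond the calibrated length range is refused", {
  curve <- fitGrowthCurve(growthCalibrationPairs())
  expect_error(estimateAge(curve, 30), "extrapolation")
  expect_error(estimateAge(curve, 400), "extrapolation")
})

test_that("too few or degenerate calibration points are refused", {
  expect_error(fitGrowthCurve(data.frame(age_years = c(1, 2, 3),
                                         femur_length_mm = c(70, 90, 100))),
               "4 distinct")
  expect_error(fitGrowthCurve(data.frame(age_years = rep(1:2, 4),
                                         femur_length_mm = rnorm(8, 100))),
               "4 distinct")
})

test_that("coefficient recovery improves with sample size", {
  curve <- defaultGrowthCurve()
  rmse <- sapply(c(8, 64), function(n) {
    errs <- sapply(1:20, function(s) {
      f <- suppressWarnings(  # tiny-n refits may be non-monotone
        fitGrowthCurve(simulateGrowthPairs(curve, n, noiseSd = 5,
                                           seed = 1000 + s)))
      sqrt(sum((growthCoefficients(f) - growthCoefficients(curve))^2))
    })
    mean(errs)
  })
  expect_lt(rmse[2], rmse[1])
})
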