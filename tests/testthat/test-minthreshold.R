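test_that("valley of a two-spike histogram follows the low-intensity tie rule", {
  h <- numeric(256)
  h[10 + 1] <- 500   # intensity 10
  h[240 + 1] <- 400  # intensity 240
  ## every interior bin is an equally empty valley: tie broken downward
  expect_identical(minimumThreshold(h), 11L)
})

test_that("threshold separates two Gaussian intensity modes almost perfectly", {
  set.seed(7)
  bg <- pmin(pmax(round(rnorm(20000, 30, 8)), 0), 255)
  bone <- pmin(pmax(round(rnorm(15000, 200, 10)), 0), 255)
  h <- tabulate(c(bg, bone) + 1L, 256L)
  thr <- minimumThreshold(h)
  expect_gt(thr, 60)
  expect_lt(thr, 170)
  expect_gte(mean(bone > thr), 0.99)  # almost all bone classified as bone
  expect_gte(mean(bg <= thr), 0.99)
})

test_that("histograms without bimodal structure are refused", {
  expect_error(minimumThreshold(rep(5, 256)), "no bimodal")
  expect_error(minimumThreshold(numeric(256)), "empty")
  one <- numeric(256); one[100] <- 10
  expect_error(minimumThreshold(one), "no bimodal")
})

test_that("smoothing reduces a noisy bimodal histogram to exactly two modes", {
  set.seed(1)
  x <- seq(0, 255)
  h <- 400 * exp(-((x - 40) / 15)^2) + 300 * exp(-((x - 210) / 20)^2) +
    runif(256, 0, 30)
  thr <- minimumThreshold(h)
  expect_gt(thr, 60)
  expect_lt(thr, 190)
})
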