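## Closed-form oracle values used below were computed from the standard
## ellipse/annulus formulas: TA = pi a b, MA = pi ai bi,
## Ix = pi (a b^3 - ai bi^3)/4, Iy = pi (a^3 b - ai^3 bi)/4.

test_that("annulus truth matches the closed forms", {
  t1 <- annulusTruth(c(10, 10), c(5, 5))
  expect_equal(t1[["TA_mm2"]], pi * 100)           # 314.159
  expect_equal(t1[["MA_mm2"]], pi * 25)            # 78.540
  expect_equal(t1[["CA_mm2"]], pi * 75)            # 235.619
  expect_equal(t1[["medullary_index"]], 0.25)
  expect_equal(t1[["imax_imin_ratio"]], 1)

  t2 <- annulusTruth(c(10, 5), c(6, 3))
  expect_equal(t2[["Ix_mm4"]], pi * (10 * 125 - 6 * 27) / 4)  # 854.513
  expect_equal(t2[["Iy_mm4"]], pi * (1000 * 5 - 216 * 3) / 4) # 3417.96
  expect_equal(t2[["ix_iy_ratio"]], 0.25)
  expect_equal(t2[["imax_imin_ratio"]], 4)
})

test_that("truth identity TA = CA + MA holds for arbitrary specs", {
  set.seed(5)
  for (i in 1:20) {
    a <- runif(1, 5, 12); b <- a * runif(1, 0.4, 1)
    s <- runif(1, 0.2, 0.8)
    t <- annulusTruth(c(a, b), s * c(a, b), poreFraction = runif(1, 0, 0.3))
    expect_equal(t[["TA_mm2"]], t[["CA_mm2"]] + t[["MA_mm2"]])
    expect_gte(t[["Imax_mm4"]], t[["Imin_mm4"]])
    expect_true(t[["medullary_index"]] >= 0 && t[["medullary_index"]] <= 1)
  }
})

test_that("rasterized section area converges to the closed form", {
  truthTA <- pi * 10 * 10
  errs <- sapply(c(0.1, 0.025), function(px) {
    ph <- makeSectionPhantom(c(10, 10), c(5, 5), pixelSize = px, seed = 2)
    relErr(sectionGeometry(ph$section)@TA, truthTA)
  })
  expect_lt(errs[1], 0.01)            # within 1 percent already at 0.1 mm
  expect_lte(errs[2], errs[1] / 2)    # at least halved at 4x finer pixels
})

test_that("degenerate cavity gives MA = 0 and medullary index 0", {
  ph <- makeSectionPhantom(c(10, 10), c(0, 0), pixelSize = 0.1, seed = 1)
  g <- suppressWarnings(sectionGeometry(ph$section))
  expect_identical(g@MA, 0)
  expect_identical(g@medullaryIndex, 0)
  expect_equal(g@CA, g@TA)
})

test_that("planted pore area honours the 0.5 percentage-point contract", {
  for (pf in c(0.05, 0.10, 0.20)) {
    ph <- makeSectionPhantom(c(10, 5), c(6, 3), poreFraction = pf,
                             pixelSize = 0.05, seed = 9)
    planted <- ph$plantedPoreArea / (pi * (10 * 5 - 6 * 3))
    expect_lt(abs(planted - pf), 0.005)
  }
})

test_that("oversized pores are refused rather than silently under-planted", {
  ## cortical thickness 1 mm; 2 mm pores cannot fit
  expect_error(
    makeSectionPhantom(c(10, 10), c(9, 9), poreFraction = 0.1,
                       pixelSize = 0.1, poreRadiusMm = 1, seed = 1),
    "infeasible pore packing")
})

test_that("in-plane rotation leaves the principal moments unchanged", {
  ph0 <- makeSectionPhantom(c(10, 5), c(6, 3), pixelSize = 0.05, seed = 3)
  ph30 <- makeSectionPhantom(c(10, 5), c(6, 3), pixelSize = 0.05, seed = 3,
                             rotationDeg = 30)
  g0 <- sectionGeometry(ph0$section)
  g30 <- sectionGeometry(ph30$section)
  expect_lt(relErr(g30@Imax, g0@Imax), 0.01)
  expect_lt(relErr(g30@Imin, g0@Imin), 0.01)
  expect_lt(abs(g30@thetaDeg - 30), 1.5)
  expect_lt(abs(g0@thetaDeg), 0.5)
})

test_that("phantom generation is a pure function of its seed", {
  a <- makeSectionPhantom(c(9, 6), c(4, 3), poreFraction = 0.1,
                          pixelSize = 0.1, noiseSd = 8, seed = 77)
  b <- makeSectionPhantom(c(9, 6), c(4, 3), poreFraction = 0.1,
                          pixelSize = 0.1, noiseSd = 8, seed = 77)
  expect_identical(a$section@intensities, b$section@intensities)
  expect_identical(a$truth, b$truth)
})
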