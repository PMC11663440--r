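test_that("a centred square has the textbook second moments", {
  ## 2 mm square at 0.02 mm pixels: Ix = Iy = s^4/12, Ixy = 0
  n <- 100
  region <- matrix(TRUE, n, n)
  mom <- secondMoments(region, 0.02)
  expect_lt(relErr(mom[["Ix"]], 2^4 / 12), 5e-3)
  expect_lt(relErr(mom[["Iy"]], 2^4 / 12), 5e-3)
  expect_equal(mom[["Ixy"]], 0, tolerance = 1e-12)
  expect_equal(mom[["Imax"]] / mom[["Imin"]], 1, tolerance = 1e-9)
  expect_error(secondMoments(matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2), 1),
               "degenerate")
})

test_that("elliptical annulus areas and moments match the closed forms", {
  ph <- makeSectionPhantom(c(10, 5), c(6, 3), pixelSize = 0.05, noiseSd = 8,
                           seed = 31)
  g <- sectionGeometry(ph$section)
  expect_lt(relErr(g@TA, pi * 50), 0.01)
  expect_lt(relErr(g@MA, pi * 18), 0.02)
  expect_lt(relErr(g@CA, pi * 32), 0.02)
  expect_lt(relErr(g@medullaryIndex, 0.36), 0.02)
  expect_lt(relErr(g@Ix, 854.513), 0.02)
  expect_lt(relErr(g@Iy, 3417.96), 0.02)
  expect_lt(relErr(g@imaxIminRatio, 4), 0.02)
  expect_lt(relErr(g@ixIyRatio, 0.25), 0.02)
  expect_lt(abs(g@thetaDeg), 0.5)
})

test_that("periosteal outline is insensitive to interior pores", {
  solid <- makeSectionPhantom(c(8, 6), c(4, 3), pixelSize = 0.05, seed = 12)
  porous <- makeSectionPhantom(c(8, 6), c(4, 3), poreFraction = 0.15,
                               pixelSize = 0.05, seed = 12)
  c1 <- periostealContour(solid$section, 110)
  c2 <- periostealContour(porous$section, 110)
  expect_equal(c1@enclosedArea, c2@enclosedArea)
})

test_that("a disjoint debris blob does not perturb the contour", {
  ph <- makeSectionPhantom(c(8, 6), c(4, 3), pixelSize = 0.1, seed = 4)
  img <- ph$section@intensities
  img[2:6, 2:6] <- 200  # small bright blob far from the bone
  sec <- new("CrossSectionImage", intensities = img, pixelSize = 0.1,
             provenance = "debris")
  c1 <- periostealContour(ph$section, 110)
  c2 <- periostealContour(sec, 110)
  expect_equal(c1@enclosedArea, c2@enclosedArea)
})

test_that("endocortical ellipse recovers the planted cavity axes", {
  ph <- makeSectionPhantom(c(10, 5), c(6, 3), pixelSize = 0.05, seed = 21)
  ell <- endocorticalEllipse(ph$section, NULL, 110)
  ax <- sort(ell@semiAxes, decreasing = TRUE)
  expect_lt(relErr(ax[1], 6), 0.02)
  expect_lt(relErr(ax[2], 3), 0.02)
})

test_that("scalloped endocortical borders still yield a stable ellipse", {
  ph <- makeSectionPhantom(c(10, 5), c(6, 3), pixelSize = 0.05,
                           scallopPores = 10L, seed = 8)
  ell <- endocorticalEllipse(ph$section, NULL, 110)
  MA <- pi * prod(ell@semiAxes)
  expect_lt(relErr(MA, pi * 18), 0.05)
})

test_that("porosity index tracks the planted pore fraction and is monotone", {
  fractions <- c(0.02, 0.05, 0.10, 0.20)
  measured <- sapply(fractions, function(pf) {
    ph <- makeSectionPhantom(c(10, 5), c(6, 3), poreFraction = pf,
                             pixelSize = 0.05, noiseSd = 8, seed = 13)
    sectionGeometry(ph$section)@porosityIndex
  })
  expect_true(all(abs(measured - fractions) < 0.02))
  expect_true(all(diff(measured) > 0))
  ## pore-free section is exactly pore-free
  ph0 <- makeSectionPhantom(c(10, 5), c(6, 3), pixelSize = 0.05,
                            noiseSd = 8, seed = 13)
  expect_identical(sectionGeometry(ph0$section)@CPA, 0)
})

test_that("section quantification is deterministic", {
  ph <- makeSectionPhantom(c(9, 7), c(5, 4), poreFraction = 0.08,
                           pixelSize = 0.05, noiseSd = 8, seed = 6)
  g1 <- as.data.frame(sectionGeometry(ph$section))
  g2 <- as.data.frame(sectionGeometry(ph$section))
  expect_identical(g1, g2)
})

test_that("near-circular sections report Imax/Imin barely above 1", {
  ph <- makeSectionPhantom(c(8, 8), c(4, 4), pixelSize = 0.05, noiseSd = 8,
                           seed = 17)
  g <- sectionGeometry(ph$section)
  expect_gte(g@imaxIminRatio, 1)
  expect_lt(g@imaxIminRatio, 1.05)
})

test_that("structural identities hold across randomized sections", {
  set.seed(99)
  for (i in 1:8) {
    a <- runif(1, 6, 11); b <- a * runif(1, 0.5, 0.95)
    s <- runif(1, 0.35, 0.65)
    pf <- sample(c(0, 0.05, 0.12), 1)
    ph <- makeSectionPhantom(c(a, b), s * c(a, b), poreFraction = pf,
                             pixelSize = 0.08, noiseSd = 8, seed = 100 + i)
    g <- sectionGeometry(ph$section)
    expect_lt(abs(g@TA - (g@CA + g@MA)), 1e-9 * g@TA)
    expect_lt(abs(g@Imax + g@Imin - (g@Ix + g@Iy)),
              1e-9 * (g@Ix + g@Iy))
    expect_gte(g@imaxIminRatio, 1)
    expect_true(g@medullaryIndex >= 0 && g@medullaryIndex <= 1)
    expect_true(g@porosityIndex >= 0 && g@porosityIndex <= 1)
  }
})

test_that("scale equivariance: coarser pixels leave mm outputs stable", {
  g1 <- sectionGeometry(
    makeSectionPhantom(c(10, 6), c(5, 3), pixelSize = 0.05, seed = 3)$section)
  g2 <- sectionGeometry(
    makeSectionPhantom(c(10, 6), c(5, 3), pixelSize = 0.1, seed = 3)$section)
  expect_lt(relErr(g2@TA, g1@TA), 0.03)
  expect_lt(relErr(g2@Ix, g1@Ix), 0.03)
  expect_lt(relErr(g2@Iy, g1@Iy), 0.03)
})
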