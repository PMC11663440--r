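test_that("cohort generation is a pure function of its spec and seed", {
  a <- makeCohort(cohortSpec(nIndividuals = 20, seed = 55))
  b <- makeCohort(cohortSpec(nIndividuals = 20, seed = 55))
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth, b$truth)
  c <- makeCohort(cohortSpec(nIndividuals = 20, seed = 56))
  expect_false(identical(a$truth, c$truth))
})

test_that("noise-free cohorts sit exactly on the trajectories", {
  spec <- cohortSpec(nIndividuals = 15,
                     noiseSds = c(medullary = 0, porosityCv = 0, shape = 0,
                                  femurLength = 0), seed = 2)
  co <- makeCohort(spec)
  expect_equal(co$truth$medullary_index,
               medullaryTrajectory(co$truth$age_years,
                                   spec@medullaryTrajectory))
  expect_equal(co$truth$porosity_index,
               porosityTrajectory(co$truth$age_years,
                                  spec@porosityTrajectory))
  expect_equal(co$metadata$femur_length_mm,
               predictLength(spec@growthCurve, co$truth$age_years))
})

test_that("the true medullary trajectory has a single interior maximum", {
  grid <- seq(0.05, 12.6, length.out = 400)
  v <- medullaryTrajectory(grid)
  peaks <- which(diff(sign(diff(v))) == -2) + 1
  expect_length(peaks, 1)
  expect_lt(abs(grid[peaks] - 2.5), 0.1)
})

test_that("derived phantom geometry realises the true indices exactly", {
  co <- makeCohort(cohortSpec(nIndividuals = 10, seed = 4))
  t <- co$truth
  expect_equal((t$inner_a * t$inner_b) / (t$outer_a * t$outer_b),
               t$medullary_index)
  expect_equal((t$outer_b / t$outer_a)^2, t$ix_iy_ratio)
})

test_that("rendered cohort volumes carry the specified porosity and shape", {
  spec <- cohortSpec(nIndividuals = 2, ageRangeYears = c(6, 12), seed = 21)
  co <- makeCohort(spec, renderVolumes = TRUE, voxelSizeMm = 0.3)
  expect_length(co$volumes, 2)
  expect_s4_class(co$volumes[[1]], "VoxelVolume")
})

test_that("growth pairs fall on the cubic when noise-free and refit recovers it", {
  curve <- defaultGrowthCurve()
  p0 <- simulateGrowthPairs(curve, 16, noiseSd = 0, seed = 3)
  expect_equal(p0$femur_length_mm, predictLength(curve, p0$age_years))
  refit <- fitGrowthCurve(p0)
  expect_equal(unname(growthCoefficients(refit)),
               unname(growthCoefficients(curve)), tolerance = 1e-6)
  ## coefficient error shrinks as noise vanishes
  err <- sapply(c(5, 0.5), function(sd) {
    f <- fitGrowthCurve(simulateGrowthPairs(curve, 64, noiseSd = sd, seed = 7))
    sqrt(sum((growthCoefficients(f) - growthCoefficients(curve))^2))
  })
  expect_lt(err[2], err[1])
  expect_error(simulateGrowthPairs(curve, 3), "at least 4")
})
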