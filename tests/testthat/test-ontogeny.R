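test_that("stage binning reproduces the reference sample's printed stages", {
  s <- chimpFemurSample()
  expect_identical(assignStage(s$age_years), as.integer(s$stage))
  expect_identical(as.integer(table(assignStage(s$age_years))),
                   c(2L, 5L, 2L, 7L, 4L))
  ## spot checks
  expect_identical(assignStage(0.04), 1L)
  expect_identical(assignStage(3.76), 3L)
  expect_identical(assignStage(12.57), 5L)
})

test_that("stage bins are half-open and exhaustive on [0, 13)", {
  expect_identical(assignStage(c(5 / 12, 3, 5, 10)), c(2L, 3L, 4L, 5L))
  expect_identical(assignStage(c(5 / 12 - 1e-9, 2.999999, 12.999999)),
                   c(1L, 2L, 5L))
  expect_error(assignStage(13), "outside")
  expect_error(assignStage(-0.1), "outside")
})

test_that("local regression reproduces linear data exactly", {
  set.seed(2)
  ages <- sort(runif(30, 0, 12))
  tr <- loessTrend(ages, ages)
  interior <- tr@grid > 1 & tr@grid < 11
  expect_lt(max(abs(tr@fitted[interior] - tr@grid[interior]) /
                  tr@grid[interior]), 1e-6)
})

test_that("trend fitting refuses unusable inputs", {
  expect_error(loessTrend(1:5, 1:5), "at least 8")
  expect_error(loessTrend(rep(2, 10), rnorm(10)), "equal")
  expect_error(loessTrend(1:10, rnorm(10), span = 0.2), "window")
})

test_that("trend recovers the generated medullary peak and porosity decline", {
  spec <- cohortSpec(seed = 301)
  co <- makeCohort(spec)
  mtr <- loessTrend(co$truth$age_years, co$truth$medullary_index)
  expect_lt(abs(trendPeakAge(mtr) -
                  spec@medullaryTrajectory[["peakAge"]]), 0.75)
  ptr <- loessTrend(co$truth$age_years, co$truth$porosity_index)
  expect_true(trendNonIncreasingAfter(ptr, porosityPlateauOnset()))
})

test_that("stage summaries follow the Tukey box-plot conventions", {
  ## hand-computed: {1,2,3,4,100} in stage 4 (ages within [5,10))
  ages <- c(5.5, 6, 7, 8, 9)
  ss <- stageSummaries(ages, c(1, 2, 3, 4, 100))
  expect_identical(ss$stage, 4L)
  expect_equal(ss$median, 3)
  expect_equal(ss$mean, 22)
  expect_equal(ss$q1, 2)
  expect_equal(ss$q3, 4)
  expect_equal(ss$whiskerHigh, 4)   # fence at 4 + 1.5*2 = 7
  expect_equal(ss$outliers[[1]], 100)
  ## singleton stage: degenerate but valid
  s1 <- stageSummaries(0.2, 0.5)
  expect_equal(s1$q1, s1$median)
  expect_equal(s1$median, s1$q3)
  expect_length(s1$outliers[[1]], 0)
})

test_that("cohort analysis emits one row per specimen and fraction", {
  spec <- cohortSpec(nIndividuals = 12, seed = 8)
  co <- makeCohort(spec)
  rec <- do.call(rbind, lapply(c(0.35, 0.5), function(f)
    cbind(data.frame(id = co$truth$id, fraction = f),
          co$truth[c("imax_imin_ratio", "ix_iy_ratio", "medullary_index",
                     "porosity_index")])))
  out <- runCohortAnalysis(co$metadata, rec)
  expect_equal(nrow(out$results), 24)
  expect_setequal(names(out$trends),
                  as.vector(outer(c("imax_imin_ratio", "ix_iy_ratio",
                                    "medullary_index", "porosity_index"),
                                  c("f35", "f50"), paste, sep = "_")))
  ## permutation invariance
  perm <- sample(nrow(rec))
  out2 <- runCohortAnalysis(co$metadata[rev(seq_len(12)), ], rec[perm, ])
  expect_equal(out2$results, out$results)
  ## missing fraction is reported with the offending specimen
  expect_error(runCohortAnalysis(co$metadata, rec[-1, ]),
               co$truth$id[rec$id[1] == co$truth$id][1])
})
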