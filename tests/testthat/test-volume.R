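test_that("auto binarization recovers the planted bone voxels", {
  fix <- refPhantom()
  bin <- binarizeVolume(fix$pv$volume)
  expect_lt(abs(sum(bin) / fix$pv$boneVoxelCount - 1), 0.01)
  ## explicit threshold at the known histogram valley matches auto
  bin110 <- binarizeVolume(fix$pv$volume, 110)
  expect_gt(mean(bin == bin110), 0.9999)
})

test_that("an all-background volume is refused", {
  vol <- new("VoxelVolume", intensities = array(20, c(8, 8, 8)),
             voxelSize = 0.25, provenance = "empty")
  expect_error(binarizeVolume(vol), "bimodal|foreground")
})

test_that("alignment brings a tilted phantom's long axis within 1 degree of z", {
  fix <- tiltedPhantom()
  dev <- boneCSG:::longAxisDeviation(fix$aligned@binaryVolume)
  expect_lt(dev, 1)
})

test_that("alignment is idempotent", {
  fix <- refPhantom()
  al <- fix$aligned
  al2 <- alignPrincipalAxes(al@binaryVolume, al@grayVolume, al@voxelSize,
                            provenance = "再")
  expect_lt(abs(al2@lengthMm - al@lengthMm), al@voxelSize + 1e-9)
  ## rotation close to a signed permutation of the identity
  expect_lt(max(abs(abs(al2@rotationApplied) - diag(3))), 0.05)
})

test_that("intermetaphyseal length matches the phantom spec", {
  fix <- refPhantom()
  expect_lt(abs(fix$aligned@lengthMm - 60), 0.5)
  tl <- tiltedPhantom()
  expect_lte(abs(tl$aligned@lengthMm - fix$aligned@lengthMm),
             2 * fix$aligned@voxelSize + 1e-9)
})

test_that("a spherical blob has no defined long axis", {
  n <- 21
  x <- seq_len(n) - 11
  blob <- array(outer(outer(x^2, x^2, "+"), x^2, "+") <= 64, c(n, n, n))
  expect_error(alignPrincipalAxes(blob, NULL, 1), "degenerate")
})

test_that("section extraction uses the distal-anchored rounded index", {
  ## synthetic aligned bone with a recognisable per-slice value
  nz <- 101
  bin <- array(FALSE, c(5, 5, nz + 10))
  gray <- array(0, c(5, 5, nz + 10))
  for (k in seq_len(nz)) {
    bin[2:4, 2:4, k + 5] <- TRUE
    gray[2:4, 2:4, k + 5] <- k
  }
  al <- new("AlignedBone", binaryVolume = bin, grayVolume = gray,
            voxelSize = 1, rotationApplied = diag(3), lengthMm = nz,
            provenance = "ladder")
  sec <- extractSection(al, 0.5)
  expect_equal(max(sec@intensities), 51)  # slice index 50 from distal, 0-based
  expect_error(extractSection(al, 0), "fraction")
  expect_error(extractSection(al, 1), "fraction")
})

test_that("waisted phantom sections at 35/50/65 percent match per-slice truth", {
  fix <- refPhantom()
  rec <- sectionRecords(fix)
  for (i in seq_len(nrow(rec))) {
    tr <- fix$pv$truth[fix$pv$truth$fraction == rec$fraction[i], ]
    expect_lt(relErr(rec$TA_mm2[i], tr$TA_mm2), 0.02)
    expect_lt(relErr(rec$ix_iy_ratio[i], tr$ix_iy_ratio), 0.02)
  }
  ## the waist makes the three sections genuinely different
  expect_gt(diff(range(rec$TA_mm2)) / mean(rec$TA_mm2), 0.05)
})

test_that("tilt invariance: tilted phantom reproduces reference metrics", {
  ref <- sectionRecords(refPhantom())
  tl <- sectionRecords(tiltedPhantom())
  for (col in c("TA_mm2", "ix_iy_ratio", "imax_imin_ratio"))
    expect_lt(max(relErr(tl[[col]], ref[[col]])), 0.02)
})

test_that("mirroring invariance: left-side twin reproduces reference metrics", {
  ref <- sectionRecords(refPhantom())
  mi <- sectionRecords(mirroredPhantom())
  for (col in c("TA_mm2", "MA_mm2", "ix_iy_ratio", "imax_imin_ratio"))
    expect_lt(max(relErr(mi[[col]], ref[[col]])), 0.01)
})

test_that("explicit zero in-plane rotation is the identity", {
  fix <- refPhantom()
  al2 <- orientAboutLongAxis(fix$aligned, mode = 0)
  expect_identical(al2@binaryVolume, fix$aligned@binaryVolume)
})

test_that("a pre-spun phantom is re-oriented to the ML axis", {
  sp <- phantomSpec(tiltEulerDeg = c(0, 0, 40), noiseSd = 8, seed = 5)
  pv <- makePhantomVolume(sp)
  bin <- binarizeVolume(pv$volume)
  al <- orientAboutLongAxis(
    alignPrincipalAxes(bin, pv$volume@intensities, sp@voxelSizeMm,
                       provenance = "spun"))
  g <- sectionGeometry(extractSection(al, 0.35))
  tr <- pv$truth[pv$truth$fraction == 0.35, ]
  expect_lt(relErr(g@ixIyRatio, tr$ix_iy_ratio), 0.02)
})
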