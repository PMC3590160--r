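test_that("parallax offset follows similar triangles and vanishes at range", {
  # direct evaluation: 30 mm baseline, 9.6 mm focal, 5.2 um pitch, 30 m
  expect_equal(parallaxOffsetPx(30, 9.6, 0.0052, 30),
               30 * 9.6 / (0.0052 * 30 * 1000))
  expect_equal(parallaxOffsetPx(30, 9.6, 0.0052, 30), 1.846, tolerance = 1e-3)
  # inverse proportionality and the long-range limit
  expect_equal(parallaxOffsetPx(30, 9.6, 0.0052, 60),
               parallaxOffsetPx(30, 9.6, 0.0052, 30) / 2)
  expect_lt(parallaxOffsetPx(30, 9.6, 0.0052, 1e9), 1e-6)
  expect_error(parallaxOffsetPx(30, 9.6, 0.0052, 0), "distance")
})

test_that("identity alignment leaves a stack pixel-identical", {
  stk <- bandStack(edgeImage(64), B = 3)
  out <- applyAlignment(stk, identityModel(3))
  expect_identical(pixelArray(out), pixelArray(stk))
  expect_error(applyAlignment(stk, identityModel(4)), "one entry per band")
})

test_that("alignment compensates a known translation to sub-pixel residual", {
  stk <- bandStack(edgeImage(96), B = 3)
  mod <- BandAlignmentModel(dx = c(3, 0, 0), dy = c(-2, 0, 0),
                            baseline = rep(0, 3), masterIndex = 3L)
  mis <- misalignStack(stk, mod)
  # the misaligned band really is displaced
  expect_gt(misalignmentScore(spatialProfile(mis, edgeSegment(96))), 2.5)
  al <- applyAlignment(mis, mod)
  resid <- spatialProfile(al, edgeSegment(96))
  expect_lt(max(abs(edgeOffsets(resid))), 0.25)
  # dimensions and range survive the warp
  expect_identical(dim(pixelArray(al)), dim(pixelArray(stk)))
  expect_true(all(pixelArray(al) >= 0 & pixelArray(al) <= 255, na.rm = TRUE))
})

test_that("misalign followed by alignment round-trips smooth images", {
  base <- smoothField(96, seed = 12)
  stk <- bandStack(base, B = 2)
  mod <- BandAlignmentModel(dx = c(2.3, 0), dy = c(-1.1, 0),
                            rotation = c(0.4, 0), scale = c(1.004, 1),
                            baseline = rep(0, 2), masterIndex = 2L)
  out <- applyAlignment(misalignStack(stk, mod), mod)
  d <- abs(getBand(out, 1) - base)
  # two bilinear resamplings of a 40-190 DN texture: mean error well under
  # 2 DN (~1% of the dynamic range)
  expect_lt(mean(d, na.rm = TRUE), 2)
})

test_that("translation estimation is sub-pixel accurate", {
  base <- smoothField(96, seed = 21)
  expect_equal(unname(estimateTranslation(base, base)), c(0, 0),
               tolerance = 1e-6)
  mod <- BandAlignmentModel(dx = c(5, 0), dy = c(-3, 0),
                            baseline = rep(0, 2), masterIndex = 2L)
  sl <- getBand(misalignStack(bandStack(base, 2), mod), 1)
  expect_equal(unname(estimateTranslation(base, sl)), c(5, -3),
               tolerance = 0.25)
  # with 5% additive noise the estimate stays within half a pixel
  set.seed(22)
  noisy <- sl + rnorm(length(sl), 0, 0.05 * sd(base))
  expect_equal(unname(estimateTranslation(base, noisy)), c(5, -3),
               tolerance = 0.5)
  expect_error(estimateTranslation(base, matrix(1, 96, 96)), "constant")
})

test_that("spatial profiles sample 45 points and localise edges per band", {
  stk <- bandStack(edgeImage(96), B = 3)
  pr <- spatialProfile(stk, edgeSegment(96))
  expect_equal(pr@length, 45L)
  expect_equal(dim(sampleValues(pr)), c(45L, 3L))
  expect_equal(edgeOffsets(pr), rep(0, 3))
  # constant stack: flat profiles, zero offsets
  flat <- MultibandStack(array(100, c(32, 32, 2)), c(530, 670))
  prf <- spatialProfile(flat, c(5, 16, 28, 16))
  expect_true(all(sampleValues(prf) == 100))
  expect_equal(edgeOffsets(prf), c(0, 0))
  expect_error(spatialProfile(stk, c(-5, 10, 200, 10)), "inside")
  # a band shifted along the probe shows up as its edge offset
  mod <- BandAlignmentModel(dx = c(2, 0, 0), dy = rep(0, 3),
                            baseline = rep(0, 3), masterIndex = 3L)
  mis <- misalignStack(stk, mod)
  off <- edgeOffsets(spatialProfile(mis, edgeSegment(96)))
  expect_equal(off[1L], 2, tolerance = 0.3)
  expect_equal(off[2:3], c(0, 0))
})

test_that("misalignment score is the worst per-band edge offset", {
  stk <- bandStack(edgeImage(96), B = 3)
  expect_lt(misalignmentScore(spatialProfile(stk, edgeSegment(96))), 0.05)
  mod <- BandAlignmentModel(dx = c(3, 0, 0), dy = rep(0, 3),
                            baseline = rep(0, 3), masterIndex = 3L)
  mis <- misalignStack(stk, mod)
  before <- misalignmentScore(spatialProfile(mis, edgeSegment(96)))
  expect_equal(before, 3, tolerance = 0.3)
  after <- misalignmentScore(spatialProfile(applyAlignment(mis, mod),
                                            edgeSegment(96)))
  expect_lt(after, before)
})

test_that("parallax-corrected alignment converges to the plain affine at range", {
  stk <- bandStack(edgeImage(96), B = 3)
  mod <- BandAlignmentModel(dx = c(1.5, -1, 0), dy = c(0.5, 1, 0),
                            baseline = c(33, 66, 0), masterIndex = 3L)
  near <- applyAlignment(stk, mod, distance = 30)
  far <- applyAlignment(stk, mod, distance = 1e4)
  plain <- applyAlignment(stk, mod)
  expect_gt(mean(abs(pixelArray(near) - pixelArray(plain)), na.rm = TRUE),
            mean(abs(pixelArray(far) - pixelArray(plain)), na.rm = TRUE))
  expect_lt(mean(abs(pixelArray(far) - pixelArray(plain)), na.rm = TRUE), 0.2)
  # the parallax shift itself is far below a hundredth of a pixel by 10 km
  expect_lt(parallaxOffsetPx(66, 9.6, 6.66 / 1280, 1e4), 0.02)
})

test_that("full model estimation recovers random rig perturbations", {
  base <- edgeImage(96, seed = 31)
  stk <- bandStack(base, B = 3)
  set.seed(32)
  for (i in 1:5) {
    tru <- BandAlignmentModel(dx = c(runif(2, -5, 5), 0),
                              dy = c(runif(2, -5, 5), 0),
                              rotation = c(runif(2, -1, 1), 0),
                              scale = c(runif(2, 0.99, 1.01), 1),
                              baseline = rep(0, 3), masterIndex = 3L)
    mis <- misalignStack(stk, tru)
    est <- estimateBandModel(mis)
    resid <- spatialProfile(applyAlignment(mis, est), edgeSegment(96))
    expect_lt(misalignmentScore(resid), 0.5)
  }
})
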