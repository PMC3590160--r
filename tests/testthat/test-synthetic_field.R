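test_that("scene generation is deterministic given the seed", {
  cfg <- SceneConfig(fieldWidth = 5, fieldLength = 5, nFrames = 1L,
                     weedPatchDensity = 400, gsd = 5, seed = 33L)
  s1 <- generateScene(cfg)
  s2 <- generateScene(cfg)
  expect_identical(pixelArray(sceneStack(s1)), pixelArray(sceneStack(s2)))
  expect_identical(sceneMasks(s1), sceneMasks(s2))
  s3 <- generateScene(SceneConfig(fieldWidth = 5, fieldLength = 5,
                                  nFrames = 1L, weedPatchDensity = 400,
                                  gsd = 5, seed = 34L))
  expect_false(identical(pixelArray(sceneStack(s1)),
                         pixelArray(sceneStack(s3))))
})

test_that("row centrelines match the field geometry", {
  # rows parallel to a field side: floor(100 / 0.7) + 1 lines
  expect_equal(length(rowOffsets(100, 100, 0.7, 0)), 143L)
  expect_equal(length(rowOffsets(100, 100, 0.7, 90)), 143L)
  # oblique rows intersect over the projected corner span
  off <- rowOffsets(10, 10, 0.7, 65)
  expect_equal(diff(off), rep(0.7, length(off) - 1L))
  expect_gt(length(off), 10 / 0.7)  # diagonal span exceeds the side
})

test_that("masks are exclusive, exhaustive and geometrically sound", {
  sc <- smallScene()
  cfg <- sceneConfig(sc)
  masks <- sceneMasks(sc)
  d <- dim(pixelArray(sceneStack(sc)))
  tot <- Reduce(`+`, lapply(masks, function(m) m * 1L))
  expect_true(all(tot == 1L))
  expect_equal(sum(tot), d[1L] * d[2L])
  # crop pixels hug the row centrelines; weed pixels stay off the rows
  g <- cfg@gsd / 100
  th <- cfg@rowDirection * pi / 180
  X <- matrix((seq_len(d[2L]) - 0.5) * g, d[1L], d[2L], byrow = TRUE)
  Y <- matrix((seq_len(d[1L]) - 0.5) * g, d[1L], d[2L])
  S <- X * cos(th) - Y * sin(th)
  latDist <- abs(S - round(S / cfg@rowSpacing) * cfg@rowSpacing)
  belt <- cfg@rowSpacing / 2 * 0.3
  expect_true(all(latDist[masks$crop] <= belt + 1e-9))
  expect_true(all(latDist[masks$weed] > belt - 1e-9))
  # every class is present in the fixture scene
  expect_true(all(vapply(masks, any, logical(1L))))
})

test_that("zero weed density produces an empty weed mask", {
  sc <- generateScene(SceneConfig(fieldWidth = 5, fieldLength = 5,
                                  nFrames = 1L, weedPatchDensity = 0,
                                  gsd = 5, seed = 2L))
  expect_equal(sum(sceneMasks(sc)$weed), 0L)
  expect_gt(sum(sceneMasks(sc)$crop), 0L)
})

test_that("weeds are never configured larger than the crop", {
  expect_error(SceneConfig(weedDiameter = 0.3, cropDiameter = 0.2),
               "not be larger")
})

test_that("class samples reproduce their Gaussian parameters", {
  st <- list(mean = c(40, 150), sd = c(5, 10))
  s <- generateClassSamples(st, 1e5, seed = 3L)
  expect_equal(dim(s), c(1e5L, 2L))
  for (b in 1:2)
    expect_lt(abs(mean(s[, b]) - st$mean[b]), 3 * st$sd[b] / sqrt(1e5))
  # sd = 0 collapses to the mean
  s0 <- generateClassSamples(list(mean = c(40, 150), sd = c(0, 0)), 100,
                             seed = 3L)
  expect_true(all(s0[, 1L] == 40) && all(s0[, 2L] == 150))
  # clipping respects the bit depth
  hot <- generateClassSamples(list(mean = 254, sd = 20), 1e4, seed = 4L)
  expect_true(all(hot >= 0 & hot <= 255))
})

test_that("default band statistics reproduce the target index means", {
  stats <- defaultClassBandStats()
  n <- 2e4
  crop <- indexFromSamples(generateClassSamples(stats$crop, n, 11L), "NDVI")
  weed <- indexFromSamples(generateClassSamples(stats$weed, n, 12L), "NDVI")
  soil <- indexFromSamples(generateClassSamples(stats$bare_soil, n, 13L),
                           "NDVI")
  # vegetation (crop + weeds pooled) about 0.58, bare soil about -0.16
  expect_equal(mean(c(crop, weed)), 0.58, tolerance = 0.05)
  expect_equal(mean(soil), -0.16, tolerance = 0.05)
})

test_that("misalignment and frame rendering integrate with the planner", {
  # translation-only misalignment is recovered by the estimator
  base <- smoothField(96, seed = 41)
  stk <- bandStack(base, B = 2)
  mod <- BandAlignmentModel(dx = c(3, 0), dy = c(-2, 0), baseline = c(0, 0),
                            masterIndex = 2L)
  mis <- misalignStack(stk, mod)
  expect_equal(unname(estimateTranslation(base, getBand(mis, 1))), c(3, -2),
               tolerance = 0.25)
  # identity model leaves the stack untouched
  expect_identical(pixelArray(misalignStack(stk, identityModel(2))),
                   pixelArray(stk))
})

test_that("rendered frames tile the field at the planned counts", {
  cfg <- SceneConfig(fieldWidth = 100, fieldLength = 100, gsd = 50,
                     nFrames = 9L, weedPatchDensity = 50, seed = 5L)
  sc <- generateScene(cfg)
  cam <- miniMCA6()
  fl <- FlightParams(30)
  plan <- planGrid(cam, fl)
  frames <- renderFrames(sc, cam, plan)
  expect_length(frames, 117L)
  # single-waypoint plan over a small field returns the clipped scene
  small <- generateScene(SceneConfig(fieldWidth = 5, fieldLength = 5,
                                     gsd = 10, nFrames = 1L,
                                     weedPatchDensity = 0, seed = 6L))
  p1 <- planGrid(cam, FlightParams(30, fieldWidth = 5, fieldLength = 5))
  f1 <- renderFrames(small, cam, p1)
  expect_length(f1, 1L)
  expect_identical(pixelArray(f1[[1L]]), pixelArray(sceneStack(small)))
  # the union of frame footprints covers the full field raster
  hit <- matrix(FALSE, 200, 200)
  g <- cfg@gsd / 100
  fp <- plan@footprint
  wp <- waypoints(plan)
  for (i in seq_len(nrow(wp))) {
    c0 <- max(1L, floor((wp$x[i] - fp@width / 2) / g) + 1L)
    c1 <- min(200L, ceiling((wp$x[i] + fp@width / 2) / g))
    r0 <- max(1L, floor((wp$y[i] - fp@height / 2) / g) + 1L)
    r1 <- min(200L, ceiling((wp$y[i] + fp@height / 2) / g))
    hit[r0:r1, c0:c1] <- TRUE
  }
  expect_true(all(hit))
  # consecutive along-track frames share at least the forward-lap fraction
  expect_gte(fp@width - plan@alongSpacing, fl@forwardOverlap * fp@width - 1e-9)
})
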