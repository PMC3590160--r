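test_that("panel calibration maps the panel to its reflectance and is scale invariant", {
  sc <- smallScene()
  stk <- sceneStack(sc)
  cal <- scenePanelCalibration(sc)
  refl <- calibrateReflectance(stk, cal)
  panel <- sceneMasks(sc)$panel
  for (b in seq_len(nBands(refl)))
    expect_equal(mean(getBand(refl, b)[panel]), 0.99, tolerance = 1e-9)
  # doubling all DN halves the gain and leaves the output unchanged
  px2 <- pixelArray(stk) / 2  # stay inside the DN range
  half <- MultibandStack(px2, bandCenters(stk), bitDepth(stk))
  refl2 <- calibrateReflectance(half, cal)
  expect_equal(pixelArray(refl2), pixelArray(refl), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(calibrationGains(refl2), 2 * calibrationGains(refl))
  # gains recovered from the simulated panel radiometry within 1%
  expect_equal(calibrationGains(refl),
               0.99 / sceneConfig(sc)@classBandStats$panel$mean,
               tolerance = 0.01)
})

test_that("vegetation indices follow their defining band arithmetic", {
  mk <- function(vals) # one-pixel six-band stack
    MultibandStack(array(vals, c(1, 1, 6)), miniMCA6Bands())
  ndvi <- function(nir, r) {
    v <- c(10, 10, r, 10, 10, nir)
    computeIndex(mk(v), "NDVI")[1, 1]
  }
  expect_equal(ndvi(50, 50), 0)        # NIR = R
  expect_equal(ndvi(150, 50), 0.5)     # NIR = 3R
  grey <- mk(rep(80, 6))               # R = G = B
  expect_equal(computeIndex(grey, "ExG")[1, 1], 0)
  expect_equal(computeIndex(grey, "NGRDI")[1, 1], 0)
  # zero denominators are flagged invalid, not imputed
  expect_true(is.na(computeIndex(mk(rep(0, 6)), "NDVI")[1, 1]))
  # missing NIR band
  rgb <- MultibandStack(array(80, c(1, 1, 3)), c(450, 530, 670))
  expect_error(computeIndex(rgb, "NDVI"), "NIR")
  expect_equal(computeIndex(rgb, "NGRDI")[1, 1], 0)
})

test_that("index images respect their analytic ranges and scale invariance", {
  sc <- smallScene()
  stk <- sceneStack(sc)
  for (ix in c("NDVI", "NGRDI")) {
    img <- computeIndex(stk, ix)
    expect_true(all(img >= -1 & img <= 1, na.rm = TRUE))
  }
  exg <- computeIndex(stk, "ExG")
  expect_true(all(exg >= -2 & exg <= 2, na.rm = TRUE))
  # global positive rescaling of all bands leaves every index unchanged
  scaled <- MultibandStack(pixelArray(stk) * 0.37, bandCenters(stk),
                           bitDepth(stk))
  for (ix in c("NDVI", "NGRDI", "ExG"))
    expect_equal(computeIndex(scaled, ix), computeIndex(stk, ix),
                 tolerance = 1e-12)
})

test_that("class sampling pools ROI pixels under the raster convention", {
  img <- matrix(7, 20, 30)
  s <- sampleClassPixels(img, matrix(TRUE, 20, 30), "crop")
  expect_true(all(sampleValues(s) == 7))
  # two disjoint axis-aligned polygons: sample size is the summed pixel count
  img2 <- matrix(seq_len(600) / 600, 20, 30)
  rois <- list(cbind(x = c(0, 10, 10, 0), y = c(0, 0, 5, 5)),
               cbind(x = c(20, 25, 25, 20), y = c(10, 10, 18, 18)))
  s2 <- sampleClassPixels(img2, rois, "weed")
  expect_equal(length(sampleValues(s2)), 10 * 5 + 5 * 8)
  expect_equal(s2@nRois, 2L)
  # NA pixels are excluded from the sample
  img3 <- matrix(c(NA, 1, 2, NA), 2, 2)
  s3 <- sampleClassPixels(img3, matrix(TRUE, 2, 2), "bare_soil")
  expect_equal(sort(sampleValues(s3)), c(1, 2))
  expect_error(sampleClassPixels(img3, matrix(c(TRUE, FALSE, FALSE, FALSE),
                                              2, 2), "crop"),
               "no valid pixels")
})

test_that("class sampling recovers generator statistics on ground-truth masks", {
  sc <- smallScene()
  cfg <- sceneConfig(sc)
  stk <- sceneStack(sc)
  masks <- sceneMasks(sc)
  for (cl in c("crop", "weed", "bare_soil")) {
    band1 <- getBand(stk, 1)
    s <- sampleClassPixels(band1, masks[[cl]], cl)
    v <- sampleValues(s)
    se <- cfg@classBandStats[[cl]]$sd[1] / sqrt(length(v))
    expect_lt(abs(mean(v) - cfg@classBandStats[[cl]]$mean[1]), 2 * se + 1e-9)
  }
})

test_that("the M-statistic matches its defining arithmetic", {
  a <- ClassSample("vegetation", "NDVI", c(0.5, 0.6, 0.7))
  expect_equal(mStatistic(a, a), 0)
  # hand evaluation on the printed 30 m multispectral NDVI summary:
  # means 0.58 and -0.16, SDs 0.07 and 0.01 give (0.58+0.16)/0.08 = 9.25
  set.seed(5)
  v1 <- rnorm(4e5, 0.58, 0.07)
  v2 <- rnorm(4e5, -0.16, 0.01)
  expect_equal(mStatistic(v1, v2), 9.25, tolerance = 0.02)
  # antisymmetry
  b <- ClassSample("bare_soil", "NDVI", c(-0.2, -0.1, -0.15))
  expect_equal(mStatistic(a, b), -mStatistic(b, a))
  expect_error(mStatistic(c(1, 1, 1), c(1, 1, 1)), "degenerate")
})

test_that("M on Gaussian samples converges to the analytic value", {
  set.seed(6)
  n <- 1e5
  m <- mStatistic(rnorm(n, 0.2, 0.05), rnorm(n, 0.05, 0.03))
  analytic <- (0.2 - 0.05) / (0.05 + 0.03)
  # sds of the estimate shrink like 1/sqrt(n); 3 SE is ~0.02 here
  expect_equal(m, analytic, tolerance = 0.02)
})

test_that("ANOVA + LSD separates distinct groups and not identical ones", {
  set.seed(7)
  far <- anovaLsd(list(a = rnorm(30, 0, 1), b = rnorm(30, 10, 1)))
  expect_lt(far$anova$p, 0.01)
  expect_true(far$pairs$distinct[1])
  expect_false(far$letters[["a"]] == far$letters[["b"]])
  # three groups, two identical + one far: the identical pair shares a letter
  r3 <- anovaLsd(list(lo1 = rnorm(25, 0), lo2 = rnorm(25, 0.02),
                      hi = rnorm(25, 8)))
  expect_true(r3$letters[["lo1"]] == r3$letters[["lo2"]])
  expect_false(r3$letters[["hi"]] == r3$letters[["lo1"]])
  expect_error(anovaLsd(list(a = 1, b = c(1, 2))), "at least two values")
  expect_error(anovaLsd(list(a = c(1, 2))), "two groups")
})

test_that("LSD keeps its nominal size under the null", {
  set.seed(8)
  hits <- 0L
  nsim <- 500
  for (i in seq_len(nsim)) {
    r <- anovaLsd(list(a = rnorm(15), b = rnorm(15)), alpha = 0.01)
    hits <- hits + r$pairs$distinct[1L]
  }
  expect_gte(hits / nsim, 0.001)
  expect_lte(hits / nsim, 0.03)
})

test_that("separability table has the Table-3 row structure", {
  sc <- smallScene()
  masks <- sceneMasks(sc)
  rois <- list(crop = masks$crop, weed = masks$weed,
               bare_soil = masks$bare_soil)
  tab <- separabilityTable(list(
    list(camera = "multispectral", altitude = 30, stack = sceneStack(sc),
         rois = rois)))
  expect_equal(nrow(tab), 6L)  # 3 indices x 2 pairs
  expect_setequal(unique(tab$pair),
                  c("vegetation_vs_bare_soil", "crop_vs_weed"))
  expect_true(all(c("max1", "min1", "mean1", "sd1", "max2", "min2", "mean2",
                    "sd2", "anova_p", "lsd_distinct", "M") %in% names(tab)))
  expect_true(all(tab$min1 <= tab$mean1 & tab$mean1 <= tab$max1))
  expect_true(all(tab$min2 <= tab$mean2 & tab$mean2 <= tab$max2))
  # M is consistent with the row statistics
  expect_equal(tab$M, (tab$mean1 - tab$mean2) / (tab$sd1 + tab$sd2))
  # no NIR band -> no NDVI rows, reported as absent rather than failing
  rgbPx <- pixelArray(sceneStack(sc))[, , 1:3]
  rgb <- MultibandStack(rgbPx, c(450, 530, 670))
  tabRGB <- separabilityTable(list(
    list(camera = "RGB", altitude = 30, stack = rgb, rois = rois)))
  expect_false("NDVI" %in% tabRGB$index)
  expect_equal(nrow(tabRGB), 4L)
  # identically generated classes are inseparable
  set.seed(9)
  same <- matrix(rnorm(4000, 0.3, 0.05), 40, 100)
  maskA <- matrix(FALSE, 40, 100); maskA[, 1:50] <- TRUE
  sA <- sampleClassPixels(same, maskA, "crop")
  sB <- sampleClassPixels(same, !maskA, "weed")
  expect_lt(abs(mStatistic(sA, sB)), 0.2)
  lsd <- anovaLsd(list(crop = sampleValues(sA), weed = sampleValues(sB)))
  expect_true(lsd$letters[["crop"]] == lsd$letters[["weed"]])
})
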