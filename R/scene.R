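# run expr under a fixed seed without disturbing the caller's RNG stream
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Default per-class per-band digital-number statistics
#'
#' Gaussian mean/sd digital numbers (8-bit scale) for the five rendered
#' classes over the six camera bands (450, 530, 670, 700, 740, 780 nm).
#' The crop, weed and bare-soil values are back-solved from the vegetation
#' index summary statistics observed at 30 m with the six-band camera
#' (vegetation NDVI about 0.58, bare soil about -0.16, crop 0.61, weed
#' 0.55, and the corresponding NGRDI/ExG means), since per-band class
#' radiometry is not observable from index summaries alone; several band
#' configurations are consistent with the same index statistics and this is
#' one of them. Frame pixels emulate the white 1 x 1 m sampling frames and
#' panel pixels the reflectance panel.
#'
#' @return named list with elements `bare_soil`, `crop`, `weed`, `frame`,
#'   `panel`, each a list of numeric `mean` and `sd` (length 6).
#' @export
defaultClassBandStats <- function() {
  list(
    bare_soil = list(mean = c(44, 75, 120, 118, 95, 87),
                     sd = rep(1.5, 6)),
    crop = list(mean = c(64.6, 65, 40, 45, 110, 165),
                sd = c(5, 6, 7, 7, 8, 12)),
    weed = list(mean = c(45.8, 44.2, 40, 44, 95, 138),
                sd = c(5, 6, 7, 7, 8, 12)),
    frame = list(mean = rep(240, 6), sd = rep(3, 6)),
    panel = list(mean = rep(250, 6), sd = rep(1.5, 6))
  )
}

#' Construct a synthetic scene configuration
#'
#' Defaults describe the study field: a 100 x 100 m sunflower plot with
#' crop rows 0.7 m apart at direction angle 65 degrees, weed patches
#' between the rows, 49 white 1 x 1 m sampling frames on a regular grid, a
#' 1 x 1 m reflectance panel at the field centre, rendered at the 1.63 cm
#' ground sampling distance of the six-band camera flown at 30 m.
#'
#' @param fieldWidth,fieldLength field extent, m.
#' @param rowSpacing crop row spacing, m.
#' @param rowDirection row direction, degrees clockwise from north (the
#'   field length axis).
#' @param cropDiameter crop plant diameter, m (4-6 leaf sunflower).
#' @param cropSpacing intra-row plant spacing, m.
#' @param weedPatchDensity weed patches per hectare.
#' @param weedPatchRadius weed patch radius, m.
#' @param weedDiameter weed plant diameter, m; weeds are similar in size to
#'   or smaller than the crop, so this must not exceed `cropDiameter`.
#' @param nFrames number of white sampling frames.
#' @param panelSize reflectance-panel side, m.
#' @param panelReflectance panel reflectance.
#' @param gsd rendered ground sampling distance, cm.
#' @param bandCenters band centre wavelengths, nm.
#' @param classBandStats per-class per-band DN statistics
#'   (see [defaultClassBandStats()]).
#' @param bitDepth sensor bit depth.
#' @param seed RNG seed; the scene is deterministic given the seed.
#' @return A [SceneConfig-class].
#' @export
SceneConfig <- function(fieldWidth = 100, fieldLength = 100,
                        rowSpacing = 0.7, rowDirection = 65,
                        cropDiameter = 0.18, cropSpacing = 0.25,
                        weedPatchDensity = 150, weedPatchRadius = 0.3,
                        weedDiameter = 0.10, nFrames = 49L, panelSize = 1,
                        panelReflectance = 0.99, gsd = 1.63,
                        bandCenters = miniMCA6Bands(),
                        classBandStats = defaultClassBandStats(),
                        bitDepth = 8L, seed = 1L) {
  new("SceneConfig", fieldWidth = as.numeric(fieldWidth),
      fieldLength = as.numeric(fieldLength),
      rowSpacing = as.numeric(rowSpacing),
      rowDirection = as.numeric(rowDirection),
      cropDiameter = as.numeric(cropDiameter),
      cropSpacing = as.numeric(cropSpacing),
      weedPatchDensity = as.numeric(weedPatchDensity),
      weedPatchRadius = as.numeric(weedPatchRadius),
      weedDiameter = as.numeric(weedDiameter), nFrames = as.integer(nFrames),
      panelSize = as.numeric(panelSize),
      panelReflectance = as.numeric(panelReflectance), gsd = as.numeric(gsd),
      bandCenters = as.numeric(bandCenters), classBandStats = classBandStats,
      bitDepth = as.integer(bitDepth), seed = as.integer(seed))
}

#' Signed offsets of the crop-row centrelines crossing a field
#'
#' Rows run along the unit vector at `rowDirection` degrees clockwise from
#' the field length axis; centrelines sit at integer multiples of
#' `rowSpacing` along the row normal. Returns the multiples whose line
#' intersects the field rectangle.
#'
#' @param fieldWidth,fieldLength field extent, m.
#' @param rowSpacing row spacing, m.
#' @param rowDirection degrees clockwise from the length axis.
#' @return numeric vector of centreline offsets (m) along the row normal.
#' @examples
#' length(rowOffsets(100, 100, 0.7, 0))  # 143 rows when parallel to a side
#' @export
rowOffsets <- function(fieldWidth, fieldLength, rowSpacing, rowDirection) {
  th <- rowDirection * pi / 180
  corners <- rbind(c(0, 0), c(fieldWidth, 0), c(0, fieldLength),
                   c(fieldWidth, fieldLength))
  s <- corners[, 1L] * cos(th) - corners[, 2L] * sin(th)
  ks <- ceiling(min(s) / rowSpacing):floor(max(s) / rowSpacing)
  ks * rowSpacing
}

#' Render a synthetic multiband crop-field scene
#'
#' Rasterises the field described by a [SceneConfig-class]: crop plants as
#' filled discs placed along the row centrelines with small positional
#' jitter, weed patches (clusters of smaller discs) centred on the inter-row
#' midlines and clipped away from the crop-row zone, white sampling frames
#' on a regular grid, and the reflectance panel at the field centre. Pixel
#' digital numbers are drawn per band from the Gaussian statistics of the
#' pixel's class and clipped to the bit depth. Mask precedence where
#' geometry overlaps: panel > frame > crop > weed > soil, which keeps the
#' class masks mutually exclusive and jointly exhaustive. Deterministic
#' given the config seed.
#'
#' @param config a [SceneConfig-class].
#' @return A [SyntheticScene-class].
#' @rdname generateScene
#' @export
setMethod("generateScene", "SceneConfig", function(config) {
  validObject(config)
  .withSeed(config@seed, .renderScene(config))
})

.renderScene <- function(cfg) {
  g <- cfg@gsd / 100                      # m per pixel
  W <- max(1L, round(cfg@fieldWidth / g))
  H <- max(1L, round(cfg@fieldLength / g))
  th <- cfg@rowDirection * pi / 180
  u <- c(sin(th), cos(th))                # along-row unit vector (x, y)
  nrm <- c(cos(th), -sin(th))             # row normal
  px <- (seq_len(W) - 0.5) * g            # pixel-centre x (m)
  py <- (seq_len(H) - 0.5) * g
  X <- matrix(px, H, W, byrow = TRUE)
  Y <- matrix(py, H, W)
  S <- X * nrm[1L] + Y * nrm[2L]          # lateral (row-normal) coordinate
  latDist <- abs(S - round(S / cfg@rowSpacing) * cfg@rowSpacing)
  rowZone <- cfg@rowSpacing / 2 * 0.3     # crop belt half-width around rows

  stamp <- function(mask, cx, cy, radius) {
    for (i in seq_along(cx)) {
      c0 <- max(1L, floor((cx[i] - radius) / g)); c1 <- min(W, ceiling((cx[i] + radius) / g))
      r0 <- max(1L, floor((cy[i] - radius) / g)); r1 <- min(H, ceiling((cy[i] + radius) / g))
      if (c0 > c1 || r0 > r1) next
      dx2 <- (px[c0:c1] - cx[i])^2
      dy2 <- (py[r0:r1] - cy[i])^2
      mask[r0:r1, c0:c1] <- mask[r0:r1, c0:c1] |
        outer(dy2, dx2, "+") <= radius^2
    }
    mask
  }

  # crop plants along each row centreline
  offs <- rowOffsets(cfg@fieldWidth, cfg@fieldLength, cfg@rowSpacing,
                     cfg@rowDirection)
  corners <- rbind(c(0, 0), c(cfg@fieldWidth, 0), c(0, cfg@fieldLength),
                   c(cfg@fieldWidth, cfg@fieldLength))
  tRange <- range(corners %*% u)
  cropMask <- matrix(FALSE, H, W)
  rCrop <- cfg@cropDiameter / 2
  maxLat <- max(0, rowZone - rCrop)       # keeps crop pixels inside the belt
  for (s0 in offs) {
    ts <- seq(tRange[1L], tRange[2L], by = cfg@cropSpacing)
    if (!length(ts)) next
    ts <- ts + stats::runif(length(ts), -0.2, 0.2) * cfg@cropSpacing
    lat <- s0 + stats::runif(length(ts), -maxLat, maxLat)
    cx <- ts * u[1L] + lat * nrm[1L]
    cy <- ts * u[2L] + lat * nrm[2L]
    keep <- cx > -rCrop & cx < cfg@fieldWidth + rCrop &
            cy > -rCrop & cy < cfg@fieldLength + rCrop
    cropMask <- stamp(cropMask, cx[keep], cy[keep], rCrop)
  }
  cropMask <- cropMask & latDist <= rowZone

  # weed patches on the inter-row midlines
  weedMask <- matrix(FALSE, H, W)
  areaHa <- cfg@fieldWidth * cfg@fieldLength / 1e4
  nPatch <- stats::rpois(1L, cfg@weedPatchDensity * areaHa)
  rWeed <- cfg@weedDiameter / 2
  if (nPatch > 0L) {
    pcx <- stats::runif(nPatch, 0, cfg@fieldWidth)
    pcy <- stats::runif(nPatch, 0, cfg@fieldLength)
    sP <- pcx * nrm[1L] + pcy * nrm[2L]
    sMid <- (floor(sP / cfg@rowSpacing) + 0.5) * cfg@rowSpacing
    pcx <- pcx + (sMid - sP) * nrm[1L]
    pcy <- pcy + (sMid - sP) * nrm[2L]
    for (k in seq_len(nPatch)) {
      nPl <- 3L + stats::rpois(1L, 7)
      ang <- stats::runif(nPl, 0, 2 * pi)
      rad <- cfg@weedPatchRadius * sqrt(stats::runif(nPl))
      weedMask <- stamp(weedMask, pcx[k] + rad * cos(ang),
                        pcy[k] + rad * sin(ang), rWeed)
    }
  }
  weedMask <- weedMask & latDist > rowZone   # weeds stay off the rows

  # white sampling frames on a regular grid
  frameMask <- matrix(FALSE, H, W)
  if (cfg@nFrames > 0L) {
    side <- ceiling(sqrt(cfg@nFrames))
    centres <- expand.grid(
      fx = ((seq_len(side)) - 0.5) / side * cfg@fieldWidth,
      fy = ((seq_len(side)) - 0.5) / side * cfg@fieldLength
    )[seq_len(cfg@nFrames), ]
    half <- 0.5                                # 1 x 1 m frames
    for (k in seq_len(nrow(centres)))
      frameMask <- frameMask |
        (abs(X - centres$fx[k]) <= half & abs(Y - centres$fy[k]) <= half)
  }

  panelMask <- abs(X - cfg@fieldWidth / 2) <= cfg@panelSize / 2 &
               abs(Y - cfg@fieldLength / 2) <= cfg@panelSize / 2

  # precedence: panel > frame > crop > weed > soil
  label <- matrix("bare_soil", H, W)
  label[weedMask] <- "weed"
  label[cropMask] <- "crop"
  label[frameMask] <- "frame"
  label[panelMask] <- "panel"
  masks <- lapply(c(bare_soil = "bare_soil", crop = "crop", weed = "weed",
                    frame = "frame", panel = "panel"),
                  function(cl) label == cl)

  maxDN <- 2^cfg@bitDepth - 1
  nb <- length(cfg@bandCenters)
  pix <- array(0, c(H, W, nb))
  for (b in seq_len(nb)) {
    band <- matrix(0, H, W)
    for (cl in names(masks)) {
      n <- sum(masks[[cl]])
      if (n == 0L) next
      st <- cfg@classBandStats[[cl]]
      band[masks[[cl]]] <- pmin(pmax(
        stats::rnorm(n, st$mean[b], st$sd[b]), 0), maxDN)
    }
    pix[, , b] <- band
  }
  new("SyntheticScene",
      stack = MultibandStack(pix, cfg@bandCenters, cfg@bitDepth),
      masks = masks, config = cfg)
}

#' @rdname accessors
#' @export
setMethod("sceneStack", "SyntheticScene", function(x) x@stack)

#' @rdname accessors
#' @export
setMethod("sceneMasks", "SyntheticScene", function(x) x@masks)

#' @rdname accessors
#' @export
setMethod("sceneConfig", "SyntheticScene", function(x) x@config)

setMethod("show", "SyntheticScene", function(object) {
  d <- dim(object@stack@pixels)
  counts <- vapply(object@masks, sum, numeric(1L))
  cat(sprintf("SyntheticScene: %.0f x %.0f m at %.2f cm/px (%d x %d px, %d bands)\n",
              object@config@fieldWidth, object@config@fieldLength,
              object@config@gsd, d[1L], d[2L], d[3L]),
      " class pixels:", paste(names(counts), counts, sep = "=",
                              collapse = "  "), "\n")
  invisible(NULL)
})

#' Draw per-band Gaussian class samples
#'
#' Fixture generator for the separability statistics: `n` pixels drawn per
#' band from a class's Gaussian DN statistics, clipped to the valid DN
#' range. Reproducible by seed.
#'
#' @param classStats list with numeric `mean` and `sd`, one value per band.
#' @param n number of samples.
#' @param seed RNG seed (`NULL` to use the current stream).
#' @param bitDepth DN bit depth for clipping.
#' @return n x B matrix of DN values.
#' @export
generateClassSamples <- function(classStats, n, seed = NULL, bitDepth = 8L) {
  stopifnot(n > 0, all(classStats$sd >= 0))
  maxDN <- 2^bitDepth - 1
  .withSeed(seed, {
    sapply(seq_along(classStats$mean), function(b)
      pmin(pmax(stats::rnorm(n, classStats$mean[b], classStats$sd[b]), 0),
           maxDN))
  })
}

#' Vegetation-index values of per-band class samples
#'
#' Treats an n x B sample matrix (rows = pixels) as an n x 1 image stack
#' and computes an index with [computeIndex()].
#'
#' @param samples matrix from [generateClassSamples()].
#' @param indexName `"NDVI"`, `"NGRDI"` or `"ExG"`.
#' @param bandCenters band centre wavelengths, nm.
#' @param bitDepth DN bit depth.
#' @return numeric vector of index values.
#' @export
indexFromSamples <- function(samples, indexName,
                             bandCenters = miniMCA6Bands(), bitDepth = 8L) {
  stk <- MultibandStack(array(samples, c(nrow(samples), 1L, ncol(samples))),
                        bandCenters, bitDepth)
  as.numeric(computeIndex(stk, indexName))
}

#' Synthetically misalign a stack
#'
#' Applies the inverse of each band's affine (about the image centre) so
#' that [applyAlignment()] with the same model restores the stack; optional
#' Gaussian sensor noise is added afterwards and values are clipped to the
#' bit depth. Used to create misaligned test frames with known ground
#' truth.
#'
#' @param stack a [MultibandStack-class].
#' @param model a [BandAlignmentModel-class].
#' @param noiseSd sd of additive Gaussian sensor noise, DN.
#' @param seed RNG seed for the noise.
#' @return the misaligned [MultibandStack-class].
#' @rdname misalignStack
#' @export
setMethod("misalignStack", signature("MultibandStack", "BandAlignmentModel"),
function(stack, model, noiseSd = 0, seed = NULL) {
  if (length(model@dx) != nBands(stack))
    stop("model must have one entry per band")
  maxDN <- 2^bitDepth(stack) - 1
  px <- stack@pixels
  .withSeed(seed, {
    for (b in seq_len(nBands(stack))) {
      if (b != model@masterIndex)
        px[, , b] <- .warpBand(stack@pixels[, , b], model@dx[b], model@dy[b],
                               model@rotation[b], model@scale[b],
                               inverse = TRUE)
      if (noiseSd > 0) {
        band <- px[, , b]
        ok <- !is.na(band)
        band[ok] <- pmin(pmax(band[ok] +
          stats::rnorm(sum(ok), 0, noiseSd), 0), maxDN)
        px[, , b] <- band
      }
    }
  })
  MultibandStack(px, bandCenters(stack), bitDepth(stack), masterIndex(stack))
})

#' Crop per-waypoint frames out of a scene
#'
#' Extracts, for every waypoint of a mission plan, the sub-image of the
#' scene raster covered by that waypoint's footprint (nearest-neighbour
#' crop; the analysis assumes nadir imaging over flat terrain, so no
#' perspective model is applied). Footprints extending beyond the field are
#' clipped to the scene.
#'
#' @param scene a [SyntheticScene-class].
#' @param camera the [CameraSpec-class] flown.
#' @param plan a [MissionPlan-class] generated for the scene's field.
#' @return list of [MultibandStack-class] frames, one per waypoint.
#' @rdname renderFrames
#' @export
setMethod("renderFrames",
          signature("SyntheticScene", "CameraSpec", "MissionPlan"),
function(scene, camera, plan) {
  g <- scene@config@gsd / 100
  d <- dim(scene@stack@pixels)
  fp <- plan@footprint
  wp <- plan@waypoints
  lapply(seq_len(nrow(wp)), function(i) {
    c0 <- max(1L, floor((wp$x[i] - fp@width / 2) / g) + 1L)
    c1 <- min(d[2L], ceiling((wp$x[i] + fp@width / 2) / g))
    r0 <- max(1L, floor((wp$y[i] - fp@height / 2) / g) + 1L)
    r1 <- min(d[1L], ceiling((wp$y[i] + fp@height / 2) / g))
    MultibandStack(scene@stack@pixels[r0:r1, c0:c1, , drop = FALSE],
                   bandCenters(scene@stack), bitDepth(scene@stack),
                   masterIndex(scene@stack))
  })
})

#' Panel calibration taken from a scene's ground truth
#'
#' @param scene a [SyntheticScene-class].
#' @return A [PanelCalibration-class] using the scene's panel mask and
#'   configured panel reflectance.
#' @export
scenePanelCalibration <- function(scene) {
  PanelCalibration(scene@masks$panel, scene@config@panelReflectance)
}
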