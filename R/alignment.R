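#' Construct a band alignment model
#'
#' Per-band affine calibration of a multi-lens camera: translation (px),
#' rotation (degrees) and scale of each slave channel relative to the master
#' channel, plus the lateral lens baseline (mm) that drives the
#' distance-dependent parallax offset. The default baselines place the six
#' lenses on a 2 x 3 grid with 33 mm spacing, the master lens at one grid
#' position; actual rig geometry can be supplied instead.
#'
#' @param dx,dy per-band translations, px.
#' @param rotation per-band rotations, degrees.
#' @param scale per-band scale factors.
#' @param baseline per-band lateral lens offsets from the master lens, mm.
#' @param masterIndex master band index.
#' @param focalLength lens focal length, mm.
#' @param pixelPitch sensor pixel pitch, mm.
#' @return A [BandAlignmentModel-class].
#' @export
BandAlignmentModel <- function(dx, dy, rotation = rep(0, length(dx)),
                               scale = rep(1, length(dx)),
                               baseline = defaultBaselines(length(dx),
                                                           masterIndex),
                               masterIndex = length(dx),
                               focalLength = 9.6, pixelPitch = 6.66 / 1280) {
  new("BandAlignmentModel", dx = as.numeric(dx), dy = as.numeric(dy),
      rotation = as.numeric(rotation), scale = as.numeric(scale),
      baseline = as.numeric(baseline), masterIndex = as.integer(masterIndex),
      focalLength = as.numeric(focalLength),
      pixelPitch = as.numeric(pixelPitch))
}

#' Identity alignment model for n bands
#'
#' @param n number of bands.
#' @param masterIndex master band index.
#' @inheritParams BandAlignmentModel
#' @return A [BandAlignmentModel-class] with identity parameters and zero
#'   baselines.
#' @export
identityModel <- function(n, masterIndex = n, focalLength = 9.6,
                          pixelPitch = 6.66 / 1280) {
  BandAlignmentModel(dx = rep(0, n), dy = rep(0, n), baseline = rep(0, n),
                     masterIndex = masterIndex, focalLength = focalLength,
                     pixelPitch = pixelPitch)
}

#' Lateral lens baselines for an n-lens 2 x 3 rig
#'
#' Euclidean distance (mm) of each lens centre from the master lens on a
#' 2 x 3 grid with `spacing` mm between adjacent lens centres.
#'
#' @param n number of lenses (<= 6).
#' @param masterIndex lens treated as master.
#' @param spacing grid spacing, mm.
#' @return numeric vector of baselines, 0 at the master.
#' @export
defaultBaselines <- function(n, masterIndex = n, spacing = 33) {
  grid <- expand.grid(col = 0:2, row = 0:1)[seq_len(n), ]
  d <- sqrt((grid$col - grid$col[masterIndex])^2 +
            (grid$row - grid$row[masterIndex])^2) * spacing
  as.numeric(d)
}

setMethod("show", "BandAlignmentModel", function(object) {
  cat("BandAlignmentModel:", length(object@dx), "bands, master",
      object@masterIndex, "\n")
  print(data.frame(dx = round(object@dx, 3), dy = round(object@dy, 3),
                   rot_deg = round(object@rotation, 4),
                   scale = round(object@scale, 5),
                   baseline_mm = object@baseline))
  invisible(NULL)
})

#' Parallax offset between two lenses
#'
#' Lenses separated laterally by `baseline` see a subject at `distance`
#' shifted by `baseline * focal / (pitch * distance)` pixels (similar
#' triangles; the factor 1000 converts the metre distance to mm). The offset
#' vanishes as distance grows, which is why a calibration taken at long
#' range needs additional offsets at close range.
#'
#' @param baseline lateral lens separation, mm.
#' @param focalLength focal length, mm.
#' @param pixelPitch sensor pixel pitch, mm.
#' @param distance subject distance, m.
#' @return offset in pixels.
#' @examples
#' parallaxOffsetPx(30, 9.6, 0.0052, 30)  # ~1.85 px
#' @export
parallaxOffsetPx <- function(baseline, focalLength, pixelPitch, distance) {
  stopifnot(baseline >= 0, focalLength > 0, pixelPitch > 0)
  if (any(distance <= 0)) stop("distance must be > 0")
  baseline * focalLength / (pixelPitch * distance * 1000)
}

# ---- internal resampling helpers -------------------------------------------

# bilinear sample of img (H x W matrix) at continuous 1-based coords
# (X = column, Y = row); NA outside the frame or where a support pixel is NA
.bilinearSample <- function(img, X, Y) {
  H <- nrow(img); W <- ncol(img)
  ok <- X >= 1 & X <= W & Y >= 1 & Y <= H
  # clamp the support cell so exact right/bottom boundary points interpolate
  # from the last cell with weight 1 instead of falling outside
  x0 <- pmin(pmax(floor(X), 1), W - 1)
  y0 <- pmin(pmax(floor(Y), 1), H - 1)
  wx <- X - x0; wy <- Y - y0
  i00 <- (x0 - 1) * H + y0
  v <- (1 - wx) * (1 - wy) * img[i00] +
       wx * (1 - wy) * img[i00 + H] +
       (1 - wx) * wy * img[i00 + 1] +
       wx * wy * img[i00 + H + 1]
  v[!ok] <- NA_real_
  v
}

# Affine warp of one band. Forward convention: the returned image `out`
# satisfies out(p) = img(T(p)) with T(p) = scale * R(theta) (p - c) + c + t,
# c the image centre, t = (dx, dy) in (column, row) pixels. With
# inverse = TRUE it returns out(q) = img(T^-1(q)) instead, so warping with a
# model and then warping with the same model forward restores the image.
.warpBand <- function(img, dx, dy, theta = 0, scale = 1, inverse = FALSE) {
  H <- nrow(img); W <- ncol(img)
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  xs <- matrix(seq_len(W), H, W, byrow = TRUE)
  ys <- matrix(seq_len(H), H, W)
  th <- theta * pi / 180
  if (!inverse) {
    X <- scale * (cos(th) * (xs - cx) - sin(th) * (ys - cy)) + cx + dx
    Y <- scale * (sin(th) * (xs - cx) + cos(th) * (ys - cy)) + cy + dy
  } else {
    u <- xs - cx - dx; v <- ys - cy - dy
    X <- (cos(th) * u + sin(th) * v) / scale + cx
    Y <- (-sin(th) * u + cos(th) * v) / scale + cy
  }
  matrix(.bilinearSample(img, X, Y), H, W)
}

.bandTranslation <- function(model, band, distance) {
  par <- if (is.finite(distance))
    parallaxOffsetPx(model@baseline[band], model@focalLength,
                     model@pixelPitch, distance) else 0
  c(model@dx[band] + par, model@dy[band])
}

#' Register slave bands onto the master grid
#'
#' Resamples every slave band by its affine calibration (translation plus,
#' at finite `distance`, the parallax offset along x; rotation and scale
#' about the image centre) onto the master band's grid using bilinear
#' interpolation. Samples falling outside the slave frame become `NA`
#' (flagged invalid) rather than zero, so they cannot bias index statistics.
#' The master band and the stack dimensions are unchanged.
#'
#' @param stack a [MultibandStack-class].
#' @param model a [BandAlignmentModel-class] with one entry per band.
#' @param distance subject distance in m used for the parallax term;
#'   `Inf` (default) disables it.
#' @return the aligned [MultibandStack-class].
#' @rdname applyAlignment
#' @export
setMethod("applyAlignment", signature("MultibandStack", "BandAlignmentModel"),
function(stack, model, distance = Inf) {
  if (length(model@dx) != nBands(stack))
    stop("model must have one entry per band")
  px <- stack@pixels
  for (b in seq_len(nBands(stack))) {
    if (b == model@masterIndex) next
    t <- .bandTranslation(model, b, distance)
    px[, , b] <- .warpBand(stack@pixels[, , b], t[1L], t[2L],
                           model@rotation[b], model@scale[b])
  }
  MultibandStack(px, bandCenters(stack), bitDepth(stack),
                 masterIndex(stack))
})

#' Estimate the translation between two images
#'
#' Cross-correlation over the full frame (computed with FFTs) locates the
#' integer shift; a 3-point parabolic fit through the correlation peak along
#' each axis refines it to sub-pixel precision. The returned `(dx, dy)` is
#' the shift of the slave's content relative to the master, i.e.
#' `slave(x, y) ~ master(x - dx, y - dy)`, matching the translation slots of
#' [BandAlignmentModel-class].
#'
#' @param master,slave numeric matrices of equal dimensions.
#' @return numeric `c(dx, dy)` in pixels.
#' @export
estimateTranslation <- function(master, slave) {
  stopifnot(identical(dim(master), dim(slave)))
  m <- master; s <- slave
  m[is.na(m)] <- mean(m, na.rm = TRUE)
  s[is.na(s)] <- mean(s, na.rm = TRUE)
  if (stats::sd(m) == 0 || stats::sd(s) == 0)
    stop("translation is undefined for a constant image")
  m <- m - mean(m); s <- s - mean(s)
  H <- nrow(m); W <- ncol(m)
  cc <- Re(stats::fft(Conj(stats::fft(m)) * stats::fft(s), inverse = TRUE))
  pk <- arrayInd(which.max(cc), dim(cc))
  refine <- function(idx, n, along) {
    get <- function(k) {
      k <- ((k - 1) %% n) + 1
      if (along == "row") cc[k, pk[2L]] else cc[pk[1L], k]
    }
    c0 <- get(idx); cm <- get(idx - 1); cp <- get(idx + 1)
    den <- cm - 2 * c0 + cp
    d <- if (den != 0) 0.5 * (cm - cp) / den else 0
    sh <- (idx - 1) + max(min(d, 0.5), -0.5)
    if (sh > n / 2) sh <- sh - n
    sh
  }
  dy <- refine(pk[1L], H, "row")
  dx <- refine(pk[2L], W, "col")
  c(dx = dx, dy = dy)
}

#' Estimate translation, rotation and scale between two images
#'
#' Initialises from [estimateTranslation()] and refines all four parameters
#' by direct minimisation of the mean squared intensity difference between
#' the master and the slave warped by the candidate parameters (Nelder-Mead),
#' evaluated over pixels valid in both images. Intended for the small
#' rotations (about a degree) and near-unity scales of multi-lens rig
#' calibration.
#'
#' @param master,slave numeric matrices of equal dimensions.
#' @param rotation set `FALSE` to fit translation only.
#' @return list with `dx`, `dy`, `rotation` (degrees), `scale`.
#' @export
estimateAlignment <- function(master, slave, rotation = TRUE) {
  t0 <- estimateTranslation(master, slave)
  obj <- function(p) {
    w <- .warpBand(slave, p[1L], p[2L], p[3L], p[4L])
    d <- w - master
    mean(d^2, na.rm = TRUE)
  }
  if (!rotation)
    return(list(dx = unname(t0[1L]), dy = unname(t0[2L]),
                rotation = 0, scale = 1))
  fit <- stats::optim(c(t0[1L], t0[2L], 0, 1), obj, method = "Nelder-Mead",
                      control = list(parscale = c(1, 1, 0.2, 0.005),
                                     maxit = 400, reltol = 1e-10))
  list(dx = unname(fit$par[1L]), dy = unname(fit$par[2L]),
       rotation = unname(fit$par[3L]), scale = unname(fit$par[4L]))
}

#' Estimate a full per-band alignment model from a stack
#'
#' Runs [estimateAlignment()] of every slave band against the master band
#' and assembles the results into a [BandAlignmentModel-class]. Used when no
#' vendor calibration is available (e.g. for synthetically misaligned
#' stacks).
#'
#' @param stack a [MultibandStack-class].
#' @param rotation fit rotation/scale as well as translation.
#' @return A [BandAlignmentModel-class] with zero baselines.
#' @export
estimateBandModel <- function(stack, rotation = TRUE) {
  nb <- nBands(stack)
  mi <- masterIndex(stack)
  master <- getBand(stack, mi)
  dx <- dy <- rot <- numeric(nb); sc <- rep(1, nb)
  for (b in seq_len(nb)) {
    if (b == mi) next
    f <- estimateAlignment(master, getBand(stack, b), rotation = rotation)
    dx[b] <- f$dx; dy[b] <- f$dy; rot[b] <- f$rotation; sc[b] <- f$scale
  }
  BandAlignmentModel(dx, dy, rot, sc, baseline = rep(0, nb), masterIndex = mi)
}

#' Sample per-band spectral values along a line
#'
#' The band-to-band registration quality probe: samples every band at
#' `length` evenly spaced points (bilinear) along a segment crossing a
#' contrast edge, then localises the edge in each band as the position of
#' the steepest intensity gradient, refined to sub-pixel precision with a
#' 3-point parabolic fit. Edge offsets are reported relative to the master
#' band; a band with no detectable edge (flat profile) gets offset 0.
#'
#' @param stack a [MultibandStack-class].
#' @param segment numeric `(x0, y0, x1, y1)` in pixel coordinates
#'   (x = column, y = row).
#' @param length number of samples (default 45).
#' @return A [ProfileReport-class].
#' @rdname spatialProfile
#' @export
setMethod("spatialProfile", "MultibandStack",
function(stack, segment, length = 45L) {
  stopifnot(is.numeric(segment), base::length(segment) == 4L, length >= 3L)
  d <- dim(stack@pixels)
  if (any(segment[c(1, 3)] < 1) || any(segment[c(1, 3)] > d[2L]) ||
      any(segment[c(2, 4)] < 1) || any(segment[c(2, 4)] > d[1L]))
    stop("segment must lie inside the image")
  n <- as.integer(length)
  tt <- seq(0, 1, length.out = n)
  X <- segment[1L] + tt * (segment[3L] - segment[1L])
  Y <- segment[2L] + tt * (segment[4L] - segment[2L])
  step <- sqrt((segment[3L] - segment[1L])^2 +
               (segment[4L] - segment[2L])^2) / (n - 1)
  vals <- sapply(seq_len(nBands(stack)), function(b)
    .bilinearSample(getBand(stack, b), X, Y))
  edgePos <- apply(vals, 2L, .edgePosition, step = step)
  mp <- edgePos[masterIndex(stack)]
  off <- edgePos - mp
  off[is.na(off)] <- 0
  new("ProfileReport", segment = as.numeric(segment), length = n,
      values = vals, edgeOffsets = off, masterIndex = masterIndex(stack))
})

# sub-pixel position (px along the profile) of the steepest gradient;
# NA for a flat profile
.edgePosition <- function(v, step) {
  g <- diff(v)
  g[is.na(g)] <- 0
  a <- abs(g)
  if (max(a) == 0) return(NA_real_)
  k <- which.max(a)
  d <- 0
  if (k > 1L && k < length(a)) {
    den <- a[k - 1L] - 2 * a[k] + a[k + 1L]
    if (den != 0) d <- max(min(0.5 * (a[k - 1L] - a[k + 1L]) / den, 0.5), -0.5)
  }
  (k - 0.5 + d) * step
}

#' @rdname accessors
#' @export
setMethod("edgeOffsets", "ProfileReport", function(x) x@edgeOffsets)

#' @rdname accessors
#' @export
setMethod("sampleValues", "ProfileReport", function(x) x@values)

setMethod("show", "ProfileReport", function(object) {
  cat(sprintf("ProfileReport: %d samples x %d bands, segment (%.1f, %.1f) -> (%.1f, %.1f)\n",
              object@length, ncol(object@values), object@segment[1L],
              object@segment[2L], object@segment[3L], object@segment[4L]),
      " edge offsets (px):",
      paste(sprintf("%.2f", object@edgeOffsets), collapse = ", "), "\n")
  invisible(NULL)
})

#' Residual misalignment of a profiled stack
#'
#' The maximum absolute per-band edge offset of a [ProfileReport-class]:
#' zero iff all bands localise the probed edge at the master band's
#' position.
#'
#' @param report a [ProfileReport-class].
#' @return misalignment in pixels.
#' @rdname misalignmentScore
#' @export
setMethod("misalignmentScore", "ProfileReport", function(report) {
  if (ncol(report@values) < 2L)
    stop("a misalignment score needs at least two bands")
  max(abs(report@edgeOffsets))
})
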