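#' Construct a panel calibration
#'
#' One-point empirical-line calibration against a near-Lambertian reference
#' panel of known reflectance (a barium-sulphate panel of reflectance 0.99
#' by default) placed in the scene.
#'
#' @param panelMask logical H x W matrix marking panel pixels (>= 30).
#' @param panelReflectance known panel reflectance.
#' @return A [PanelCalibration-class].
#' @export
PanelCalibration <- function(panelMask, panelReflectance = 0.99) {
  new("PanelCalibration", panelMask = panelMask,
      panelReflectance = as.numeric(panelReflectance))
}

#' Calibrate digital numbers to reflectance
#'
#' Per band, the gain is `panel_reflectance / mean(panel DN)` and every
#' pixel is scaled by it (one-point empirical line through the origin), so
#' panel pixels map to the panel reflectance on average. The output is scale
#' invariant: doubling all DN halves the gain and leaves the calibrated
#' stack unchanged.
#'
#' @param stack a [MultibandStack-class] of digital numbers.
#' @param calibration a [PanelCalibration-class]; the mask must match the
#'   stack dimensions.
#' @return a [MultibandStack-class] of reflectances, with per-band gains in
#'   `attr(, "gains")` of the pixel array preserved via the returned object's
#'   metadata; use [calibrationGains()] to recover them.
#' @rdname calibrateReflectance
#' @export
setMethod("calibrateReflectance",
          signature("MultibandStack", "PanelCalibration"),
function(stack, calibration) {
  validObject(calibration)
  d <- dim(stack@pixels)
  if (!identical(dim(calibration@panelMask), d[1:2]))
    stop("panel mask dimensions must match the stack")
  px <- stack@pixels
  gains <- numeric(d[3L])
  for (b in seq_len(d[3L])) {
    m <- px[, , b][calibration@panelMask]
    mu <- mean(m, na.rm = TRUE)
    if (!is.finite(mu) || mu <= 0)
      stop("zero or invalid panel digital numbers; cannot calibrate band ", b)
    gains[b] <- calibration@panelReflectance / mu
    px[, , b] <- px[, , b] * gains[b]
  }
  out <- MultibandStack(px, bandCenters(stack), bitDepth(stack),
                        masterIndex(stack))
  attr(out@pixels, "gains") <- gains
  out
})

#' Per-band gains of a calibrated stack
#'
#' @param stack a stack returned by [calibrateReflectance()].
#' @return numeric vector of reflectance-per-DN gains, or `NULL`.
#' @export
calibrationGains <- function(stack) attr(stack@pixels, "gains")

.indexNames <- c("NDVI", "NGRDI", "ExG")

#' Compute a vegetation index image
#'
#' Supported indices, on whatever radiometric scale the stack carries (raw
#' digital numbers by default, or reflectance after
#' [calibrateReflectance()]; all three are ratio/chromatic indices and are
#' invariant to a global positive rescaling of the bands):
#' \itemize{
#'   \item NDVI = (NIR - R) / (NIR + R)
#'   \item NGRDI = (G - R) / (G + R)
#'   \item ExG = 2g - r - b on chromatic coordinates r = R/(R+G+B) etc.,
#'     i.e. (2G - R - B) / (R + G + B)
#' }
#' Band roles resolve by wavelength ([bandIndex()]); with two red channels
#' the 670 nm band is used. Pixels with a zero denominator or any `NA`
#' input are flagged invalid (`NA`).
#'
#' @param stack a [MultibandStack-class].
#' @param indexName `"NDVI"`, `"NGRDI"` or `"ExG"`.
#' @return H x W numeric matrix of index values.
#' @rdname computeIndex
#' @export
setMethod("computeIndex", "MultibandStack", function(stack, indexName) {
  indexName <- match.arg(indexName, .indexNames)
  need <- switch(indexName, NDVI = c("NIR", "R"), NGRDI = c("G", "R"),
                 ExG = c("R", "G", "B"))
  idx <- vapply(need, function(r) bandIndex(stack, r), integer(1L))
  if (anyNA(idx))
    stop(indexName, " requires band(s) ",
         paste(need[is.na(idx)], collapse = ", "),
         " which the stack does not provide")
  bands <- lapply(idx, function(i) getBand(stack, i))
  names(bands) <- need
  out <- switch(indexName,
    NDVI = {
      den <- bands$NIR + bands$R
      (bands$NIR - bands$R) / den
    },
    NGRDI = {
      den <- bands$G + bands$R
      (bands$G - bands$R) / den
    },
    ExG = {
      den <- bands$R + bands$G + bands$B
      (2 * bands$G - bands$R - bands$B) / den
    })
  out[!is.finite(out)] <- NA_real_
  out
})
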