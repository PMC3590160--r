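#' Construct a multiband image stack
#'
#' @param pixels numeric H x W x B array of digital numbers (a matrix is
#'   promoted to a single-band array).
#' @param bandCenters band centre wavelengths, nm.
#' @param bitDepth radiometric resolution in bits (8 or 10 for the supported
#'   cameras).
#' @param masterIndex index of the master band (defaults to the last band,
#'   the NIR channel of the six-lens camera).
#' @return A [MultibandStack-class].
#' @examples
#' px <- array(runif(20 * 20 * 6, 0, 255), c(20, 20, 6))
#' s <- MultibandStack(px, miniMCA6Bands(), bitDepth = 8)
#' nBands(s)
#' @export
MultibandStack <- function(pixels, bandCenters, bitDepth = 8L,
                           masterIndex = length(bandCenters)) {
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 1L))
  storage.mode(pixels) <- "double"
  new("MultibandStack", pixels = pixels,
      bandCenters = as.numeric(bandCenters),
      bitDepth = as.integer(bitDepth), masterIndex = as.integer(masterIndex))
}

#' @rdname accessors
#' @export
setMethod("nBands", "MultibandStack", function(x) dim(x@pixels)[3L])

#' @rdname accessors
#' @export
setMethod("bandCenters", "MultibandStack", function(x) x@bandCenters)

#' @rdname accessors
#' @export
setMethod("bitDepth", "MultibandStack", function(x) x@bitDepth)

#' @rdname accessors
#' @export
setMethod("masterIndex", "MultibandStack", function(x) x@masterIndex)

#' @rdname accessors
#' @export
setMethod("pixelArray", "MultibandStack", function(x) x@pixels)

#' Extract one band as a matrix
#'
#' @param stack a [MultibandStack-class].
#' @param band band index.
#' @return H x W numeric matrix.
#' @export
getBand <- function(stack, band) {
  stopifnot(band >= 1L, band <= nBands(stack))
  d <- dim(stack@pixels)
  matrix(stack@pixels[, , band], d[1L], d[2L])
}

setMethod("show", "MultibandStack", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("MultibandStack: %d x %d px, %d band(s), %d-bit, master band %d\n",
              d[1L], d[2L], d[3L], object@bitDepth, object@masterIndex),
      " band centres (nm):", paste(object@bandCenters, collapse = ", "), "\n")
  invisible(NULL)
})

# canonical wavelengths (nm) used to resolve band roles; with two red bands
# (670 and 700 nm) the 670 nm band is the red input of all indices
.roleWavelengths <- c(B = 450, G = 530, R = 670, NIR = 780)

#' Find the band serving a spectral role
#'
#' Resolves `"B"`, `"G"`, `"R"` or `"NIR"` to the band whose centre
#' wavelength is nearest the canonical wavelength for that role (450, 530,
#' 670 and 780 nm). A band further than `tol` nm from the canonical
#' wavelength does not qualify; the red role resolves to the 670 nm band
#' when a camera has two red channels.
#'
#' @param stack a [MultibandStack-class].
#' @param role one of `"B"`, `"G"`, `"R"`, `"NIR"`.
#' @param tol maximum distance from the canonical wavelength, nm.
#' @return band index, or `NA_integer_` if no band qualifies.
#' @export
bandIndex <- function(stack, role, tol = 40) {
  role <- match.arg(role, names(.roleWavelengths))
  target <- .roleWavelengths[[role]]
  d <- abs(bandCenters(stack) - target)
  i <- which.min(d)
  if (d[i] > tol) return(NA_integer_)
  as.integer(i)
}

#' Read / write a multiband stack as a multi-page TIFF
#'
#' One 16-bit grey page per band, digital numbers scaled by the stack's bit
#' depth. Band centres and master index are not stored in the TIFF and must
#' be supplied on read. `NA` pixels are written as zero.
#'
#' @param file path to a TIFF file.
#' @param bandCenters,bitDepth,masterIndex stack metadata for the read stack.
#' @param stack a [MultibandStack-class] to write.
#' @return `readMultibandTIFF` returns a [MultibandStack-class];
#'   `writeMultibandTIFF` returns the path invisibly.
#' @rdname multibandTIFF
#' @export
readMultibandTIFF <- function(file, bandCenters, bitDepth = 8L,
                              masterIndex = length(bandCenters)) {
  pages <- tiff::readTIFF(file, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != length(bandCenters))
    stop("TIFF page count does not match bandCenters")
  maxDN <- 2^bitDepth - 1
  px <- array(0, c(dim(pages[[1L]])[1:2], length(pages)))
  for (b in seq_along(pages)) {
    p <- pages[[b]]
    if (length(dim(p)) == 3L) p <- p[, , 1L]
    px[, , b] <- p * maxDN
  }
  MultibandStack(px, bandCenters, bitDepth, masterIndex)
}

#' @rdname multibandTIFF
#' @export
writeMultibandTIFF <- function(stack, file) {
  maxDN <- 2^bitDepth(stack) - 1
  pages <- lapply(seq_len(nBands(stack)), function(b) {
    m <- getBand(stack, b) / maxDN
    m[is.na(m)] <- 0
    pmin(pmax(m, 0), 1)
  })
  tiff::writeTIFF(pages, file, bits.per.sample = 16L)
  invisible(file)
}

#' Assemble per-channel TIFFs into one stack
#'
#' Multi-lens cameras store each channel as its own single-band file; this
#' reads one file per band (in the order of `files`) and stacks them.
#'
#' @param files character vector of single-band TIFF paths, one per band.
#' @inheritParams readMultibandTIFF
#' @return A [MultibandStack-class].
#' @export
assembleChannels <- function(files, bandCenters, bitDepth = 8L,
                             masterIndex = length(bandCenters)) {
  if (length(files) != length(bandCenters))
    stop("one file per band is required")
  maxDN <- 2^bitDepth - 1
  mats <- lapply(files, function(f) {
    p <- tiff::readTIFF(f)
    if (length(dim(p)) == 3L) p <- p[, , 1L]
    p * maxDN
  })
  d <- dim(mats[[1L]])
  px <- array(unlist(mats), c(d, length(mats)))
  MultibandStack(px, bandCenters, bitDepth, masterIndex)
}
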