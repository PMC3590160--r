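#' Construct a camera specification
#'
#' @param name camera label.
#' @param focalLength focal length, mm.
#' @param sensorWidth,sensorHeight physical sensor size, mm.
#' @param pixelsX,pixelsY pixel counts along sensor width and height.
#' @param bitDepth radiometric resolution, bits.
#'
#' @return A [CameraSpec-class] object.
#' @examples
#' cam <- CameraSpec("msp", 9.6, 6.66, 5.32, 1280, 1024, 10)
#' groundSamplingDistance(cam, 30)
#' @export
CameraSpec <- function(name, focalLength, sensorWidth, sensorHeight,
                       pixelsX, pixelsY, bitDepth = 8L) {
  new("CameraSpec", name = as.character(name),
      focalLength = as.numeric(focalLength),
      sensorWidth = as.numeric(sensorWidth),
      sensorHeight = as.numeric(sensorHeight),
      pixelsX = as.integer(pixelsX), pixelsY = as.integer(pixelsY),
      bitDepth = as.integer(bitDepth))
}

#' Built-in camera presets
#'
#' `miniMCA6()` returns the six-channel multispectral camera used in the
#' weed-mapping study (focal 9.6 mm, sensor 6.66 x 5.32 mm, 1280 x 1024 px,
#' 10-bit, bands at 450/530/670/700/740/780 nm). `olympusPEN()` returns the
#' 12-megapixel RGB still camera (sensor 17.3 x 13 mm, 4032 x 3024 px,
#' 8-bit). The RGB zoom lens was set near its 14 mm wide end; because the
#' effective focal length actually flown is not recoverable from the lens
#' spec alone, `olympusPEN()` accepts an effective focal-length override.
#'
#' @param effectiveFocal optional effective focal length, mm, overriding the
#'   nominal 14 mm.
#' @return A [CameraSpec-class].
#' @rdname cameraPresets
#' @export
miniMCA6 <- function() {
  CameraSpec("mini-MCA-6", focalLength = 9.6,
             sensorWidth = 6.66, sensorHeight = 5.32,
             pixelsX = 1280L, pixelsY = 1024L, bitDepth = 10L)
}

#' @rdname cameraPresets
#' @export
olympusPEN <- function(effectiveFocal = NULL) {
  CameraSpec("Olympus PEN E-PM1",
             focalLength = if (is.null(effectiveFocal)) 14 else effectiveFocal,
             sensorWidth = 17.3, sensorHeight = 13,
             pixelsX = 4032L, pixelsY = 3024L, bitDepth = 8L)
}

#' mini-MCA-6 band centre wavelengths (nm)
#' @export
miniMCA6Bands <- function() c(450, 530, 670, 700, 740, 780)

#' @rdname accessors
#' @param x an object.
#' @export
setMethod("focalLength", "CameraSpec", function(x) x@focalLength)

#' @rdname accessors
#' @export
setMethod("pixelPitch", "CameraSpec",
          function(x) x@sensorWidth / x@pixelsX)

#' @rdname accessors
#' @export
setMethod("bitDepth", "CameraSpec", function(x) x@bitDepth)

setMethod("show", "CameraSpec", function(object) {
  cat("CameraSpec:", object@name, "\n",
      sprintf(" focal %.2f mm | sensor %.2f x %.2f mm | %d x %d px | %d-bit\n",
              object@focalLength, object@sensorWidth, object@sensorHeight,
              object@pixelsX, object@pixelsY, object@bitDepth))
  invisible(NULL)
})

#' Construct flight parameters
#'
#' Defaults follow the study mission settings: a 100 x 100 m field flown with
#' 60% forward-lap, 30% side-lap, direction angle 65 degrees, 5 s dwell and
#' one image per waypoint.
#'
#' @param altitude flight altitude above ground, m.
#' @param fieldWidth,fieldLength field extent, m.
#' @param directionAngle flight-line direction, degrees clockwise from north.
#' @param forwardOverlap,sideOverlap overlap fractions in [0, 1).
#' @param dwell seconds held at each waypoint.
#' @param imagesPerWaypoint images per waypoint.
#' @return A [FlightParams-class] object.
#' @export
FlightParams <- function(altitude, fieldWidth = 100, fieldLength = 100,
                         directionAngle = 65, forwardOverlap = 0.60,
                         sideOverlap = 0.30, dwell = 5,
                         imagesPerWaypoint = 1L) {
  new("FlightParams", altitude = as.numeric(altitude),
      fieldWidth = as.numeric(fieldWidth),
      fieldLength = as.numeric(fieldLength),
      directionAngle = as.numeric(directionAngle),
      forwardOverlap = as.numeric(forwardOverlap),
      sideOverlap = as.numeric(sideOverlap),
      dwell = as.numeric(dwell),
      imagesPerWaypoint = as.integer(imagesPerWaypoint))
}

#' Construct platform kinematics
#'
#' Defaults are the quadrocopter's cruising speed (15 m/s) and climb rate
#' (7.5 m/s).
#'
#' @param cruiseSpeed horizontal speed, m/s.
#' @param climbRate vertical speed, m/s.
#' @return A [Kinematics-class] object.
#' @export
Kinematics <- function(cruiseSpeed = 15, climbRate = 7.5) {
  new("Kinematics", cruiseSpeed = as.numeric(cruiseSpeed),
      climbRate = as.numeric(climbRate))
}
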