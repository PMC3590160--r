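#' Ground sampling distance from the pinhole relation
#'
#' The ground size of one image pixel at nadir:
#' `gsd = altitude * pixel_pitch / focal_length`, with pixel pitch taken as
#' `sensor_width / pixels_x` (horizontal pitch; the vertical pitch differs by
#' well under 1% for the supported cameras). Linear in altitude.
#'
#' @param camera a [CameraSpec-class].
#' @param altitude flight altitude above ground, m (>= 0).
#' @return GSD in cm per pixel (unrounded; round to two decimals for
#'   display).
#' @examples
#' groundSamplingDistance(miniMCA6(), 30)   # ~1.63 cm
#' groundSamplingDistance(miniMCA6(), 100)  # ~5.42 cm
#' @rdname groundSamplingDistance
#' @export
setMethod("groundSamplingDistance", "CameraSpec", function(camera, altitude) {
  validObject(camera)
  stopifnot(is.numeric(altitude), all(altitude >= 0))
  # pitch and focal are both mm, so the ratio is unitless; altitude in m,
  # * 100 converts to cm
  altitude * pixelPitch(camera) / camera@focalLength * 100
})

#' Ground footprint of one image
#'
#' Each footprint axis scales the corresponding sensor dimension by
#' `altitude / focal_length`; the area is reported in hectares.
#'
#' @param camera a [CameraSpec-class].
#' @param altitude flight altitude, m (>= 0).
#' @return A [Footprint-class] with ground `width` and `height` (m), `gsd`
#'   (cm/px) and `area` (ha).
#' @examples
#' imageFootprint(miniMCA6(), 100)  # ~69 x 55 m, 0.38 ha
#' @rdname imageFootprint
#' @export
setMethod("imageFootprint", "CameraSpec", function(camera, altitude) {
  validObject(camera)
  stopifnot(is.numeric(altitude), length(altitude) == 1L, altitude >= 0)
  w <- altitude * camera@sensorWidth / camera@focalLength
  h <- altitude * camera@sensorHeight / camera@focalLength
  new("Footprint", width = w, height = h,
      gsd = groundSamplingDistance(camera, altitude),
      area = w * h / 1e4)
})

#' Lowest whole-metre altitude reaching a target GSD
#'
#' Inverts the pinhole GSD relation and rounds up to the next whole metre,
#' so the returned altitude is the smallest integer altitude whose GSD does
#' not exceed the target.
#'
#' @param camera a [CameraSpec-class].
#' @param targetGsd target ground sampling distance, cm/px (> 0).
#' @return altitude in whole metres.
#' @examples
#' altitudeForGsd(miniMCA6(), 1)  # 19 m
#' altitudeForGsd(miniMCA6(), 4)  # 74 m
#' @rdname altitudeForGsd
#' @export
setMethod("altitudeForGsd", "CameraSpec", function(camera, targetGsd) {
  validObject(camera)
  if (!is.numeric(targetGsd) || any(targetGsd <= 0))
    stop("targetGsd must be > 0")
  ceiling((targetGsd / 100) * camera@focalLength / pixelPitch(camera))
})

#' Plan a serpentine waypoint grid over a rectangular field
#'
#' Flight lines run along the field width (the direction-angle axis), so
#' forward-lap consumes the long footprint dimension and side-lap the short
#' one. Counts use a ceiling so the grid always covers the field:
#' `n_lines = ceiling(field_length / ((1 - side_overlap) * footprint_height))`
#' and `images_per_line = ceiling(field_width /
#' ((1 - forward_overlap) * footprint_width))`. Waypoints are laid out
#' serpentine (alternate lines reversed) in a local frame with the origin at
#' the field corner and x along the direction angle; the first footprint's
#' corner coincides with the field corner.
#'
#' @param camera a [CameraSpec-class].
#' @param flight a [FlightParams-class].
#' @return A [MissionPlan-class].
#' @examples
#' planGrid(miniMCA6(), FlightParams(30))   # 9 x 13 = 117 images
#' planGrid(miniMCA6(), FlightParams(100))  # 3 x 4 = 12 images
#' @rdname planGrid
#' @export
setMethod("planGrid", signature("CameraSpec", "FlightParams"),
function(camera, flight) {
  validObject(camera); validObject(flight)
  fp <- imageFootprint(camera, flight@altitude)
  if (fp@width <= 0 || fp@height <= 0)
    stop("footprint must be strictly positive; check altitude")
  along <- (1 - flight@forwardOverlap) * fp@width
  across <- (1 - flight@sideOverlap) * fp@height
  nLines <- as.integer(ceiling(flight@fieldLength / across))
  perLine <- as.integer(ceiling(flight@fieldWidth / along))
  # serpentine: odd lines fly +x, even lines -x
  wp <- do.call(rbind, lapply(seq_len(nLines), function(i) {
    xs <- (seq_len(perLine) - 1) * along + fp@width / 2
    if (i %% 2L == 0L) xs <- rev(xs)
    data.frame(x = xs, y = (i - 1) * across + fp@height / 2,
               alt = flight@altitude)
  }))
  wp$seq <- seq_len(nrow(wp))
  new("MissionPlan", nLines = nLines, imagesPerLine = perLine,
      totalImages = nLines * perLine, lineSpacing = across,
      alongSpacing = along, waypoints = wp, altitude = flight@altitude,
      directionAngle = flight@directionAngle, footprint = fp)
})

#' Images per hectare of a mission plan
#'
#' @param plan a [MissionPlan-class].
#' @param flight the [FlightParams-class] the plan was made for.
#' @return images per hectare.
#' @rdname imagesPerHectare
#' @export
setMethod("imagesPerHectare", signature("MissionPlan", "FlightParams"),
function(plan, flight) {
  areaHa <- flight@fieldWidth * flight@fieldLength / 1e4
  if (areaHa <= 0) stop("field area must be > 0")
  plan@totalImages / areaHa
})

#' Estimate mission duration
#'
#' A transparent three-term model: vertical transit (climb to altitude and
#' descend at the climb rate), serpentine cruise along the waypoint path at
#' cruising speed, and the dwell spent at each waypoint. Vendor
#' mission-planner estimates embed an unpublished speed model, so durations
#' from this function are the package's own and are not comparable to such
#' tools beyond order of magnitude.
#'
#' @param plan a [MissionPlan-class].
#' @param kinematics a [Kinematics-class].
#' @param dwell seconds per waypoint.
#' @param imagesPerWaypoint images taken per waypoint.
#' @return duration in minutes.
#' @rdname estimateFlightTime
#' @export
setMethod("estimateFlightTime", signature("MissionPlan", "Kinematics"),
function(plan, kinematics, dwell = 5, imagesPerWaypoint = 1L) {
  validObject(kinematics)
  stopifnot(dwell >= 0)
  wp <- plan@waypoints
  pathLen <- if (nrow(wp) > 1L)
    sum(sqrt(diff(wp$x)^2 + diff(wp$y)^2)) else 0
  secs <- 2 * plan@altitude / kinematics@climbRate +
    pathLen / kinematics@cruiseSpeed +
    nrow(wp) * dwell * imagesPerWaypoint
  secs / 60
})

#' @rdname accessors
#' @export
setMethod("waypoints", "MissionPlan", function(x) x@waypoints)

#' @rdname accessors
#' @export
setMethod("totalImages", "MissionPlan", function(x) x@totalImages)

setMethod("show", "Footprint", function(object) {
  cat(sprintf("Footprint: %.1f x %.1f m (%d x %d m displayed) | %.2f cm/px | %.2f ha\n",
              object@width, object@height, round(object@width),
              round(object@height), round(object@gsd, 2), object@area))
  invisible(NULL)
})

setMethod("show", "MissionPlan", function(object) {
  cat("MissionPlan:",
      sprintf("%d lines x %d images = %d images at %.0f m\n",
              object@nLines, object@imagesPerLine, object@totalImages,
              object@altitude),
      sprintf(" line spacing %.1f m | along-track spacing %.1f m | direction %.0f deg\n",
              object@lineSpacing, object@alongSpacing, object@directionAngle))
  invisible(NULL)
})

#' Write mission waypoints to CSV
#'
#' Exports columns `x_m`, `y_m`, `alt_m`, `seq` in the local field frame.
#'
#' @param plan a [MissionPlan-class].
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeWaypoints <- function(plan, file) {
  wp <- plan@waypoints
  utils::write.csv(data.frame(x_m = wp$x, y_m = wp$y, alt_m = wp$alt,
                              seq = wp$seq),
                   file, row.names = FALSE)
  invisible(file)
}
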