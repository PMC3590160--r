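#' @import methods
NULL

#' CameraSpec: optical and sensor geometry of one camera
#'
#' Holds the quantities that drive all photogrammetric mission arithmetic:
#' focal length, physical sensor dimensions and pixel counts. The pixel pitch
#' (sensor width divided by pixel count) together with focal length and flight
#' altitude fixes the ground sampling distance through the pinhole relation.
#'
#' @slot name camera label.
#' @slot focalLength focal length in mm.
#' @slot sensorWidth,sensorHeight physical sensor size in mm (width is the
#'   long image dimension).
#' @slot pixelsX,pixelsY sensor pixel counts along width and height.
#' @slot bitDepth radiometric resolution in bits.
#'
#' @seealso [CameraSpec()], [miniMCA6()], [olympusPEN()]
#' @exportClass CameraSpec
setClass("CameraSpec",
  representation(
    name = "character",
    focalLength = "numeric",
    sensorWidth = "numeric",
    sensorHeight = "numeric",
    pixelsX = "integer",
    pixelsY = "integer",
    bitDepth = "integer"
  )
)

setValidity("CameraSpec", function(object) {
  msg <- character()
  num <- c(focalLength = object@focalLength,
           sensorWidth = object@sensorWidth,
           sensorHeight = object@sensorHeight,
           pixelsX = as.numeric(object@pixelsX),
           pixelsY = as.numeric(object@pixelsY),
           bitDepth = as.numeric(object@bitDepth))
  if (any(!is.finite(num)) || any(num <= 0))
    msg <- c(msg, "all numeric camera fields must be finite and > 0")
  else {
    px <- object@sensorWidth / object@pixelsX
    py <- object@sensorHeight / object@pixelsY
    if (abs(px - py) / py > 0.10)
      msg <- c(msg, "horizontal and vertical pixel pitch differ by more than 10%")
  }
  if (length(msg)) msg else TRUE
})

#' FlightParams: mission settings for one flight
#'
#' Mirrors the inputs a waypoint-editor tool asks for: field extent, the
#' direction angle of the main field side, image overlaps and the per-waypoint
#' camera tasks.
#'
#' @slot altitude flight altitude above ground, m.
#' @slot fieldWidth,fieldLength field extent, m. Forward-lap acts along the
#'   flight line (field width), side-lap across lines (field length).
#' @slot directionAngle direction of the flight lines, degrees clockwise from
#'   north.
#' @slot forwardOverlap,sideOverlap image overlap fractions in [0, 1).
#' @slot dwell seconds the platform holds at each waypoint.
#' @slot imagesPerWaypoint photos taken per waypoint.
#'
#' @exportClass FlightParams
setClass("FlightParams",
  representation(
    altitude = "numeric",
    fieldWidth = "numeric",
    fieldLength = "numeric",
    directionAngle = "numeric",
    forwardOverlap = "numeric",
    sideOverlap = "numeric",
    dwell = "numeric",
    imagesPerWaypoint = "integer"
  )
)

setValidity("FlightParams", function(object) {
  msg <- character()
  if (!is.finite(object@altitude) || object@altitude <= 0)
    msg <- c(msg, "altitude must be > 0")
  if (object@fieldWidth <= 0 || object@fieldLength <= 0)
    msg <- c(msg, "field dimensions must be > 0")
  ov <- c(object@forwardOverlap, object@sideOverlap)
  if (any(ov < 0) || any(ov >= 1))
    msg <- c(msg, "overlaps must lie in [0, 1)")
  if (object@dwell < 0) msg <- c(msg, "dwell must be >= 0")
  if (object@imagesPerWaypoint < 1L)
    msg <- c(msg, "imagesPerWaypoint must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Kinematics: platform speeds used for flight-time estimation
#'
#' @slot cruiseSpeed horizontal cruising speed, m/s.
#' @slot climbRate vertical climb rate, m/s.
#' @exportClass Kinematics
setClass("Kinematics",
  representation(cruiseSpeed = "numeric", climbRate = "numeric")
)

setValidity("Kinematics", function(object) {
  if (object@cruiseSpeed <= 0 || object@climbRate <= 0)
    "cruiseSpeed and climbRate must be > 0" else TRUE
})

#' Footprint: ground rectangle imaged by one frame
#'
#' @slot width ground extent of the long image dimension, m.
#' @slot height ground extent of the short image dimension, m.
#' @slot gsd ground sampling distance, cm per pixel.
#' @slot area footprint area, ha.
#' @exportClass Footprint
setClass("Footprint",
  representation(width = "numeric", height = "numeric",
                 gsd = "numeric", area = "numeric")
)

setValidity("Footprint", function(object) {
  if (any(c(object@width, object@height, object@gsd, object@area) < 0))
    "footprint fields must be >= 0" else TRUE
})

#' MissionPlan: serpentine waypoint grid for one flight
#'
#' @slot nLines number of flight lines (across-track).
#' @slot imagesPerLine waypoints per line (along-track).
#' @slot totalImages `nLines * imagesPerLine`.
#' @slot lineSpacing distance between adjacent flight lines, m.
#' @slot alongSpacing distance between consecutive waypoints on a line, m.
#' @slot waypoints data.frame with columns `x`, `y`, `alt` (m, local field
#'   frame: origin at the field corner, x along the direction angle) and `seq`.
#' @slot altitude flight altitude, m.
#' @slot directionAngle degrees clockwise from north of the local x axis.
#' @slot footprint the per-image [Footprint-class].
#' @exportClass MissionPlan
setClass("MissionPlan",
  representation(
    nLines = "integer",
    imagesPerLine = "integer",
    totalImages = "integer",
    lineSpacing = "numeric",
    alongSpacing = "numeric",
    waypoints = "data.frame",
    altitude = "numeric",
    directionAngle = "numeric",
    footprint = "Footprint"
  )
)

setValidity("MissionPlan", function(object) {
  msg <- character()
  if (object@totalImages != object@nLines * object@imagesPerLine)
    msg <- c(msg, "totalImages must equal nLines * imagesPerLine")
  if (nrow(object@waypoints) != object@totalImages)
    msg <- c(msg, "waypoint count must equal totalImages")
  if (!all(c("x", "y", "alt", "seq") %in% names(object@waypoints)))
    msg <- c(msg, "waypoints must have columns x, y, alt, seq")
  if (length(msg)) msg else TRUE
})

#' MultibandStack: a B-band image with band metadata
#'
#' The unit of all image operations: an H x W x B array of digital numbers
#' (or reflectances after calibration) with the centre wavelength of each
#' band, the radiometric bit depth and the index of the master band onto
#' whose grid slave bands are registered. `NA` pixels mark invalid samples
#' (e.g. resampled from outside the frame).
#'
#' @slot pixels numeric H x W x B array.
#' @slot bandCenters centre wavelengths, nm, one per band.
#' @slot bitDepth 8 or 10 (or any positive bit count).
#' @slot masterIndex index of the master band.
#' @exportClass MultibandStack
setClass("MultibandStack",
  representation(
    pixels = "array",
    bandCenters = "numeric",
    bitDepth = "integer",
    masterIndex = "integer"
  )
)

setValidity("MultibandStack", function(object) {
  msg <- character()
  d <- dim(object@pixels)
  if (length(d) != 3L || any(d < 1L))
    msg <- c(msg, "pixels must be a 3-d array with positive dimensions")
  else {
    if (length(object@bandCenters) != d[3L])
      msg <- c(msg, "one band centre per band is required")
    if (object@masterIndex < 1L || object@masterIndex > d[3L])
      msg <- c(msg, "masterIndex out of range")
    rng <- range(object@pixels, na.rm = TRUE)
    if (is.finite(rng[1L]) &&
        (rng[1L] < 0 || rng[2L] > 2^object@bitDepth - 1))
      msg <- c(msg, sprintf("pixel values must lie in [0, %d]",
                            2^object@bitDepth - 1L))
  }
  if (object@bitDepth < 1L) msg <- c(msg, "bitDepth must be >= 1")
  if (anyDuplicated(object@bandCenters))
    msg <- c(msg, "band centres must be distinct")
  if (length(msg)) msg else TRUE
})

#' BandAlignmentModel: per-band affine calibration plus parallax geometry
#'
#' Stores, for each band, the translation (px), rotation (degrees) and scale
#' relating the slave channel to the master channel, plus the lateral lens
#' baseline (mm) used for the distance-dependent parallax offset. The master
#' band carries identity parameters. `focalLength` and `pixelPitch` (mm)
#' convert the baseline into pixels at a given subject distance.
#'
#' @slot dx,dy per-band translation, px.
#' @slot rotation per-band rotation, degrees.
#' @slot scale per-band scale factor (> 0).
#' @slot baseline per-band lateral lens offset from the master lens, mm.
#' @slot masterIndex index of the master band.
#' @slot focalLength lens focal length, mm.
#' @slot pixelPitch sensor pixel pitch, mm.
#' @exportClass BandAlignmentModel
setClass("BandAlignmentModel",
  representation(
    dx = "numeric",
    dy = "numeric",
    rotation = "numeric",
    scale = "numeric",
    baseline = "numeric",
    masterIndex = "integer",
    focalLength = "numeric",
    pixelPitch = "numeric"
  )
)

setValidity("BandAlignmentModel", function(object) {
  msg <- character()
  n <- length(object@dx)
  lens <- c(length(object@dy), length(object@rotation), length(object@scale),
            length(object@baseline))
  if (any(lens != n))
    msg <- c(msg, "per-band parameter vectors must have equal length")
  if (any(object@scale <= 0)) msg <- c(msg, "scale must be > 0")
  m <- object@masterIndex
  if (m < 1L || m > n) msg <- c(msg, "masterIndex out of range")
  else if (object@dx[m] != 0 || object@dy[m] != 0 ||
           object@rotation[m] != 0 || object@scale[m] != 1 ||
           object@baseline[m] != 0)
    msg <- c(msg, "master band must have identity parameters")
  if (object@focalLength <= 0 || object@pixelPitch <= 0)
    msg <- c(msg, "focalLength and pixelPitch must be > 0")
  if (length(msg)) msg else TRUE
})

#' ProfileReport: per-band values sampled along a short line
#'
#' The quality-control probe for band-to-band registration: spectral values
#' of every band sampled along a line (default 45 px) crossing a contrast
#' edge, plus the sub-pixel edge position of each band relative to the master.
#'
#' @slot segment numeric length-4 vector `(x0, y0, x1, y1)` in pixel
#'   coordinates.
#' @slot length number of samples along the segment.
#' @slot values length x B matrix of sampled values.
#' @slot edgeOffsets per-band edge position minus the master band's, px.
#' @slot masterIndex master band index.
#' @exportClass ProfileReport
setClass("ProfileReport",
  representation(
    segment = "numeric",
    length = "integer",
    values = "matrix",
    edgeOffsets = "numeric",
    masterIndex = "integer"
  )
)

setValidity("ProfileReport", function(object) {
  msg <- character()
  if (length(object@segment) != 4L)
    msg <- c(msg, "segment must be (x0, y0, x1, y1)")
  if (nrow(object@values) != object@length)
    msg <- c(msg, "value series length must equal the segment length")
  if (length(object@edgeOffsets) != ncol(object@values))
    msg <- c(msg, "one edge offset per band is required")
  if (length(msg)) msg else TRUE
})

#' PanelCalibration: one-point empirical-line calibration from a panel
#'
#' @slot panelMask logical H x W matrix marking reflectance-panel pixels.
#' @slot panelReflectance known panel reflectance (fraction).
#' @exportClass PanelCalibration
setClass("PanelCalibration",
  representation(panelMask = "matrix", panelReflectance = "numeric")
)

setValidity("PanelCalibration", function(object) {
  msg <- character()
  if (!is.logical(object@panelMask))
    msg <- c(msg, "panelMask must be logical")
  else if (sum(object@panelMask) < 30L)
    msg <- c(msg, "panel must contain at least 30 pixels")
  if (object@panelReflectance <= 0 || object@panelReflectance > 1)
    msg <- c(msg, "panelReflectance must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' ClassSample: per-pixel vegetation-index values for one cover class
#'
#' @slot label one of `"bare_soil"`, `"crop"`, `"weed"`, `"vegetation"`.
#' @slot indexName one of `"NDVI"`, `"NGRDI"`, `"ExG"` (or `"raw"` when the
#'   sample holds plain band values).
#' @slot values per-pixel index values.
#' @slot nRois number of sampling areas pooled.
#' @exportClass ClassSample
setClass("ClassSample",
  representation(
    label = "character",
    indexName = "character",
    values = "numeric",
    nRois = "integer"
  )
)

.classLabels <- c("bare_soil", "crop", "weed", "vegetation")

setValidity("ClassSample", function(object) {
  msg <- character()
  if (!object@label %in% .classLabels)
    msg <- c(msg, paste("label must be one of:",
                        paste(.classLabels, collapse = ", ")))
  if (length(object@values) == 0L)
    msg <- c(msg, "values must be non-empty")
  if (object@indexName %in% c("NDVI", "NGRDI")) {
    rng <- range(object@values, na.rm = TRUE)
    if (rng[1L] < -1 || rng[2L] > 1)
      msg <- c(msg, paste(object@indexName, "values must lie in [-1, 1]"))
  }
  if (length(msg)) msg else TRUE
})

#' SceneConfig: parameters of a synthetic crop-field scene
#'
#' Describes a row-crop field as rendered by [generateScene()]: field extent,
#' crop-row geometry, weed-patch layout, the layout of reference targets
#' (white sampling frames and a reflectance panel) and the per-class per-band
#' digital-number statistics of the simulated sensor.
#'
#' @slot fieldWidth,fieldLength field extent, m.
#' @slot rowSpacing crop-row spacing, m.
#' @slot rowDirection crop-row direction, degrees clockwise from north.
#' @slot cropDiameter crop plant diameter, m.
#' @slot cropSpacing intra-row plant spacing, m.
#' @slot weedPatchDensity weed patches per hectare.
#' @slot weedPatchRadius radius of a weed patch, m.
#' @slot weedDiameter weed plant diameter, m (must not exceed `cropDiameter`).
#' @slot nFrames number of white 1 x 1 m sampling frames on a regular grid.
#' @slot panelSize side of the square reflectance panel, m.
#' @slot panelReflectance reflectance of the panel (fraction).
#' @slot gsd ground sampling distance of the rendered raster, cm.
#' @slot bandCenters band centre wavelengths, nm.
#' @slot classBandStats named list (per class) of lists with numeric vectors
#'   `mean` and `sd`, one entry per band; classes `bare_soil`, `crop`,
#'   `weed`, `frame`, `panel`.
#' @slot bitDepth sensor bit depth.
#' @slot seed integer seed making the scene reproducible.
#' @exportClass SceneConfig
setClass("SceneConfig",
  representation(
    fieldWidth = "numeric",
    fieldLength = "numeric",
    rowSpacing = "numeric",
    rowDirection = "numeric",
    cropDiameter = "numeric",
    cropSpacing = "numeric",
    weedPatchDensity = "numeric",
    weedPatchRadius = "numeric",
    weedDiameter = "numeric",
    nFrames = "integer",
    panelSize = "numeric",
    panelReflectance = "numeric",
    gsd = "numeric",
    bandCenters = "numeric",
    classBandStats = "list",
    bitDepth = "integer",
    seed = "integer"
  )
)

setValidity("SceneConfig", function(object) {
  msg <- character()
  if (object@rowSpacing <= 0) msg <- c(msg, "rowSpacing must be > 0")
  if (object@gsd <= 0) msg <- c(msg, "gsd must be > 0")
  if (object@weedDiameter > object@cropDiameter)
    msg <- c(msg, "weed plants must not be larger than crop plants")
  need <- c("bare_soil", "crop", "weed", "frame", "panel")
  miss <- setdiff(need, names(object@classBandStats))
  if (length(miss))
    msg <- c(msg, paste("classBandStats missing class(es):",
                        paste(miss, collapse = ", ")))
  nb <- length(object@bandCenters)
  for (cl in intersect(need, names(object@classBandStats))) {
    st <- object@classBandStats[[cl]]
    if (!all(c("mean", "sd") %in% names(st)) ||
        length(st$mean) != nb || length(st$sd) != nb)
      msg <- c(msg, paste0("classBandStats$", cl,
                           " must have per-band mean and sd"))
    else if (any(st$sd < 0))
      msg <- c(msg, paste0("classBandStats$", cl, " sds must be >= 0"))
  }
  if (length(msg)) msg else TRUE
})

#' SyntheticScene: a rendered multiband scene plus ground truth
#'
#' @slot stack the rendered [MultibandStack-class].
#' @slot masks named list of logical H x W matrices (`bare_soil`, `crop`,
#'   `weed`, `frame`, `panel`), mutually exclusive and jointly exhaustive.
#' @slot config the [SceneConfig-class] that produced the scene.
#' @exportClass SyntheticScene
setClass("SyntheticScene",
  representation(
    stack = "MultibandStack",
    masks = "list",
    config = "SceneConfig"
  )
)

setValidity("SyntheticScene", function(object) {
  msg <- character()
  d <- dim(object@stack@pixels)[1:2]
  tot <- matrix(0L, d[1L], d[2L])
  for (m in object@masks) {
    if (!identical(dim(m), d))
      return("mask dimensions must match the stack")
    tot <- tot + m
  }
  if (any(tot != 1L))
    msg <- c(msg, "class masks must be mutually exclusive and exhaustive")
  if (length(msg)) msg else TRUE
})
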