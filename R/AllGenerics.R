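#' @rdname groundSamplingDistance
#' @export
setGeneric("groundSamplingDistance",
           function(camera, altitude) standardGeneric("groundSamplingDistance"))

#' @rdname imageFootprint
#' @export
setGeneric("imageFootprint",
           function(camera, altitude) standardGeneric("imageFootprint"))

#' @rdname altitudeForGsd
#' @export
setGeneric("altitudeForGsd",
           function(camera, targetGsd) standardGeneric("altitudeForGsd"))

#' @rdname planGrid
#' @export
setGeneric("planGrid",
           function(camera, flight) standardGeneric("planGrid"))

#' @rdname imagesPerHectare
#' @export
setGeneric("imagesPerHectare",
           function(plan, flight) standardGeneric("imagesPerHectare"))

#' @rdname estimateFlightTime
#' @export
setGeneric("estimateFlightTime",
           function(plan, kinematics, dwell = 5, imagesPerWaypoint = 1L)
             standardGeneric("estimateFlightTime"))

#' @rdname applyAlignment
#' @export
setGeneric("applyAlignment",
           function(stack, model, distance = Inf)
             standardGeneric("applyAlignment"))

#' @rdname spatialProfile
#' @export
setGeneric("spatialProfile",
           function(stack, segment, length = 45L)
             standardGeneric("spatialProfile"))

#' @rdname misalignmentScore
#' @export
setGeneric("misalignmentScore",
           function(report) standardGeneric("misalignmentScore"))

#' @rdname calibrateReflectance
#' @export
setGeneric("calibrateReflectance",
           function(stack, calibration) standardGeneric("calibrateReflectance"))

#' @rdname computeIndex
#' @export
setGeneric("computeIndex",
           function(stack, indexName) standardGeneric("computeIndex"))

#' @rdname generateScene
#' @export
setGeneric("generateScene",
           function(config) standardGeneric("generateScene"))

#' @rdname misalignStack
#' @export
setGeneric("misalignStack",
           function(stack, model, noiseSd = 0, seed = NULL)
             standardGeneric("misalignStack"))

#' @rdname renderFrames
#' @export
setGeneric("renderFrames",
           function(scene, camera, plan) standardGeneric("renderFrames"))

# ---- accessors ----

#' Accessors for the package's S4 classes
#'
#' Small read-only accessors: band metadata and pixel data of a
#' [MultibandStack-class], optics of a [CameraSpec-class], the waypoint
#' table and image count of a [MissionPlan-class], the components of a
#' [SyntheticScene-class], and the sampled values / edge offsets of a
#' [ProfileReport-class] or [ClassSample-class].
#'
#' @param x an object of the documented classes.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nBands", function(x) standardGeneric("nBands"))

#' @rdname accessors
#' @export
setGeneric("bandCenters", function(x) standardGeneric("bandCenters"))

#' @rdname accessors
#' @export
setGeneric("bitDepth", function(x) standardGeneric("bitDepth"))

#' @rdname accessors
#' @export
setGeneric("masterIndex", function(x) standardGeneric("masterIndex"))

#' @rdname accessors
#' @export
setGeneric("pixelArray", function(x) standardGeneric("pixelArray"))

#' @rdname accessors
#' @export
setGeneric("focalLength", function(x) standardGeneric("focalLength"))

#' @rdname accessors
#' @export
setGeneric("pixelPitch", function(x) standardGeneric("pixelPitch"))

#' @rdname accessors
#' @export
setGeneric("waypoints", function(x) standardGeneric("waypoints"))

#' @rdname accessors
#' @export
setGeneric("totalImages", function(x) standardGeneric("totalImages"))

#' @rdname accessors
#' @export
setGeneric("sceneStack", function(x) standardGeneric("sceneStack"))

#' @rdname accessors
#' @export
setGeneric("sceneMasks", function(x) standardGeneric("sceneMasks"))

#' @rdname accessors
#' @export
setGeneric("sceneConfig", function(x) standardGeneric("sceneConfig"))

#' @rdname accessors
#' @export
setGeneric("edgeOffsets", function(x) standardGeneric("edgeOffsets"))

#' @rdname accessors
#' @export
setGeneric("sampleValues", function(x) standardGeneric("sampleValues"))
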