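#' Read / write a camera specification as YAML
#'
#' The YAML mirrors the mission-planner field names: `name`,
#' `focal_length_mm`, `sensor_width_mm`, `sensor_height_mm`, `pixels_x`,
#' `pixels_y`, `bit_depth` and optionally `band_centers_nm`.
#'
#' @param file path to a YAML file.
#' @param camera a [CameraSpec-class].
#' @param bandCenters optional band centres to store alongside.
#' @return `readCameraYAML` returns a list with elements `camera` (a
#'   [CameraSpec-class]) and `bandCenters` (numeric or `NULL`);
#'   `writeCameraYAML` returns the path invisibly.
#' @rdname cameraYAML
#' @export
readCameraYAML <- function(file) {
  y <- yaml::read_yaml(file)
  need <- c("focal_length_mm", "sensor_width_mm", "sensor_height_mm",
            "pixels_x", "pixels_y")
  miss <- setdiff(need, names(y))
  if (length(miss))
    stop("camera YAML missing field(s): ", paste(miss, collapse = ", "))
  cam <- CameraSpec(if (is.null(y$name)) "camera" else y$name,
                    y$focal_length_mm, y$sensor_width_mm, y$sensor_height_mm,
                    y$pixels_x, y$pixels_y,
                    if (is.null(y$bit_depth)) 8L else y$bit_depth)
  list(camera = cam,
       bandCenters = if (is.null(y$band_centers_nm)) NULL
                     else as.numeric(y$band_centers_nm))
}

#' @rdname cameraYAML
#' @export
writeCameraYAML <- function(camera, file, bandCenters = NULL) {
  y <- list(name = camera@name, focal_length_mm = camera@focalLength,
            sensor_width_mm = camera@sensorWidth,
            sensor_height_mm = camera@sensorHeight,
            pixels_x = camera@pixelsX, pixels_y = camera@pixelsY,
            bit_depth = camera@bitDepth)
  if (!is.null(bandCenters)) y$band_centers_nm <- as.numeric(bandCenters)
  yaml::write_yaml(y, file)
  invisible(file)
}

#' Read / write a band alignment model as JSON
#'
#' @param file path to a JSON file.
#' @param model a [BandAlignmentModel-class].
#' @return `readAlignmentModel` returns a [BandAlignmentModel-class];
#'   `writeAlignmentModel` returns the path invisibly.
#' @rdname alignmentJSON
#' @export
readAlignmentModel <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  BandAlignmentModel(j$dx, j$dy, j$rotation, j$scale, j$baseline,
                     masterIndex = j$master_index,
                     focalLength = j$focal_length_mm,
                     pixelPitch = j$pixel_pitch_mm)
}

#' @rdname alignmentJSON
#' @export
writeAlignmentModel <- function(model, file) {
  jsonlite::write_json(
    list(dx = model@dx, dy = model@dy, rotation = model@rotation,
         scale = model@scale, baseline = model@baseline,
         master_index = model@masterIndex,
         focal_length_mm = model@focalLength,
         pixel_pitch_mm = model@pixelPitch),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Write a separability table to CSV
#'
#' @param table data.frame from [separabilityTable()].
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeSeparabilityCSV <- function(table, file) {
  utils::write.csv(table, file, row.names = FALSE)
  invisible(file)
}
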