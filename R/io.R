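# Shared format readers/writers. Grayscale images travel as numeric matrices
# [row, col] in [0, 1]; 0-based, half-open pixel coordinates at every API
# surface (x = column, y = row, origin top-left).

#' Read an image file as a grayscale matrix
#'
#' PNG or TIFF, 8- or 16-bit; RGB inputs are reduced to luminance (or kept as
#' an array with `as = "rgb"`).
#'
#' @param path Image file.
#' @param as `"gray"` (default) or `"rgb"`.
#' @return Numeric matrix (gray) or height x width x 3 array (rgb), in [0, 1].
#' @export
read_image <- function(path, as = "gray") {
  im <- EBImage::readImage(path)
  d <- EBImage::imageData(im)
  if (length(dim(d)) == 2) {
    m <- t(d)
    return(if (as == "rgb") array(rep(m, 3), c(dim(m), 3)) else m)
  }
  arr <- aperm(d[, , 1:3, drop = FALSE], c(2, 1, 3))
  if (as == "rgb") return(arr)
  0.2126 * arr[, , 1] + 0.7152 * arr[, , 2] + 0.0722 * arr[, , 3]
}

#' Write a matrix or RGB array to an image file
#'
#' @param image Matrix or height x width x 3 array in [0, 1].
#' @param path Output path (extension selects PNG/TIFF).
#' @export
write_image <- function(image, path) {
  image <- pmin(pmax(image, 0), 1)
  d <- if (length(dim(image)) == 3) aperm(image, c(2, 1, 3)) else t(image)
  im <- EBImage::Image(d, colormode = if (length(dim(image)) == 3) "Color" else "Grayscale")
  EBImage::writeImage(im, path)
  invisible(path)
}

#' Spectrum CSV I/O
#'
#' Two-column CSV (`wavelength_nm`, `intensity`).
#'
#' @param trace A [spectrum_trace()].
#' @param path File path.
#' @export
write_spectrum_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace[, c("wavelength_nm", "intensity")]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path)
  spectrum_trace(df$wavelength_nm, df$intensity)
}

#' Calibration JSON I/O
#'
#' @param calibration A `ps_calibration`.
#' @param path File path.
#' @export
write_calibration_json <- function(calibration, path) {
  jsonlite::write_json(list(coefficients = calibration$coefficients,
                            degree = calibration$degree,
                            residual_rms_nm = calibration$residual_rms_nm,
                            valid_pixel_range = calibration$valid_pixel_range),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(coefficients = j$coefficients, degree = j$degree,
                 residual_rms_nm = j$residual_rms_nm,
                 valid_pixel_range = j$valid_pixel_range),
            class = "ps_calibration")
}

#' Distortion model JSON I/O
#'
#' @param model A `ps_distortion`.
#' @param path File path.
#' @export
write_distortion_json <- function(model, path) {
  jsonlite::write_json(list(center = model$center, k1 = model$k1,
                            k2 = model$k2, r_norm = model$r_norm,
                            residual_rms_px = model$residual_rms_px),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_distortion_json
#' @export
read_distortion_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- radial_distortion_model(j$center, j$k1, j$k2, j$r_norm)
  m$residual_rms_px <- j$residual_rms_px %||% NA_real_
  m
}

#' Spectrometer geometry YAML I/O
#'
#' Keys carry units: `groove_density_lpmm`, `tube_length_mm`,
#' `entrance_slit_mm`, `detector_slit_mm`, `diffraction_order`,
#' `incidence_angle_deg`.
#'
#' @param path YAML file.
#' @export
read_geometry_yaml <- function(path) {
  g <- yaml::read_yaml(path)
  spectrometer_geometry(
    groove_density_lpmm = g$groove_density_lpmm %||% 1000,
    tube_length_mm = g$tube_length_mm %||% 77.5,
    entrance_slit_mm = g$entrance_slit_mm %||% 1,
    detector_slit_mm = g$detector_slit_mm %||% 1,
    diffraction_order = g$diffraction_order %||% 1,
    incidence_angle_deg = g$incidence_angle_deg %||% 0)
}

#' @rdname read_geometry_yaml
#' @param geometry A [spectrometer_geometry()].
#' @export
write_geometry_yaml <- function(geometry, path) {
  yaml::write_yaml(unclass(geometry), path)
  invisible(path)
}
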