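# Slit-grating phone spectrometer: grating forward model, slit-limited
# resolution, spectrum extraction from dispersed slit images, wavelength
# calibration, line-width and transmission measurements.

#' Spectrometer geometry
#'
#' A transmission grating on the phone camera fed by a baffled tube with an
#' entrance slit at the distal end and a detector-side slit at the grating:
#' the two slits over the tube length define the angular acceptance, hence
#' the spectral resolution.
#'
#' @param groove_density_lpmm Grating groove density (lines/mm).
#' @param tube_length_mm Slit-to-slit tube length (mm).
#' @param entrance_slit_mm,detector_slit_mm Slit widths (mm).
#' @param diffraction_order Working order (|m| >= 1).
#' @param incidence_angle_deg Incidence angle on the grating (degrees);
#'   default normal incidence along the tube axis.
#' @return A `ps_spec_geometry` object.
#' @examples
#' spectrometer_geometry() # the 1000 lp/mm, 77.5 mm, 1 mm slit instrument
#' @export
spectrometer_geometry <- function(groove_density_lpmm = 1000,
                                  tube_length_mm = 77.5,
                                  entrance_slit_mm = 1,
                                  detector_slit_mm = 1,
                                  diffraction_order = 1,
                                  incidence_angle_deg = 0) {
  stopifnot(groove_density_lpmm > 0, entrance_slit_mm > 0,
            detector_slit_mm > 0, abs(diffraction_order) >= 1)
  if (tube_length_mm <= 0) stop("tube length must be positive")
  structure(list(groove_density_lpmm = groove_density_lpmm,
                 tube_length_mm = tube_length_mm,
                 entrance_slit_mm = entrance_slit_mm,
                 detector_slit_mm = detector_slit_mm,
                 diffraction_order = as.integer(diffraction_order),
                 incidence_angle_deg = incidence_angle_deg),
            class = "ps_spec_geometry")
}

#' Grating diffraction angle
#'
#' Solves `sin(theta_i) + sin(theta_m) = m * lambda / d` with groove spacing
#' `d = 1e6 / groove_density` nm.
#'
#' @param wavelength_nm Wavelength(s) in nm.
#' @param geometry A [spectrometer_geometry()].
#' @return Diffraction angle(s) in degrees.
#' @examples
#' diffraction_angle(500, spectrometer_geometry()) # 30 degrees
#' @export
diffraction_angle <- function(wavelength_nm, geometry = spectrometer_geometry()) {
  d_nm <- 1e6 / geometry$groove_density_lpmm
  s <- geometry$diffraction_order * wavelength_nm / d_nm -
    sin(geometry$incidence_angle_deg * pi / 180)
  if (any(abs(s) > 1)) stop("evanescent diffraction order")
  asin(s) * 180 / pi
}

#' Predicted spectral resolution (FWHM)
#'
#' The two slits over the tube length define an angular acceptance: the
#' convolution of two rect functions, a triangle for equal slits, whose FWHM
#' is `max(w1, w2) / L` radians. That converts to wavelength through the
#' grating dispersion: `d_lambda = d * cos(theta_m) * d_theta`.
#'
#' @param geometry A [spectrometer_geometry()].
#' @param wavelength_nm Evaluation wavelength (nm).
#' @return Predicted FWHM in nm.
#' @examples
#' predict_resolution(spectrometer_geometry(), 546) # ~10.8 nm
#' @export
predict_resolution <- function(geometry = spectrometer_geometry(),
                               wavelength_nm = 546) {
  dtheta <- max(geometry$entrance_slit_mm, geometry$detector_slit_mm) /
    geometry$tube_length_mm
  thm <- diffraction_angle(wavelength_nm, geometry) * pi / 180
  d_nm <- 1e6 / geometry$groove_density_lpmm
  d_nm * cos(thm) * dtheta
}

#' Build a spectrum trace
#'
#' @param wavelength_nm Ascending wavelengths (nm).
#' @param intensity Intensities (arbitrary units), same length.
#' @param metadata Optional list (ROI, channel mode, ...).
#' @return A `ps_spectrum` tibble subclass with columns `wavelength_nm`,
#'   `intensity`.
#' @export
spectrum_trace <- function(wavelength_nm, intensity, metadata = list()) {
  stopifnot(length(wavelength_nm) == length(intensity))
  if (any(diff(wavelength_nm) <= 0)) stop("wavelengths must be strictly increasing")
  out <- tibble::tibble(wavelength_nm = wavelength_nm, intensity = intensity)
  class(out) <- c("ps_spectrum", class(out))
  attr(out, "metadata") <- metadata
  out
}

#' @export
autoplot.ps_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$wavelength_nm, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "intensity (a.u.)")
}

#' Extract a pixel-indexed spectrum from a dispersed slit image
#'
#' Averages the ROI rows (perpendicular to the horizontal dispersion axis)
#' into a 1-D trace. An optional background ROI (same x-extent) is averaged
#' the same way and subtracted.
#'
#' @param image Grayscale matrix, or a 3-channel array for RGB.
#' @param roi `c(x, y, w, h)` in 0-based, half-open pixel coordinates.
#' @param channel_mode `"sum"` (sum of RGB channels, default), `"luminance"`,
#'   or a channel index for single-channel extraction; ignored for grayscale.
#' @param background_roi Optional `c(x, y, w, h)` background region.
#' @return Tibble with `pixel` (0-based column index) and `intensity`.
#' @export
extract_spectrum <- function(image, roi = NULL, channel_mode = "sum",
                             background_roi = NULL) {
  if (length(dim(image)) == 3) {
    image <- switch(as.character(channel_mode),
      sum = image[, , 1] + image[, , 2] + image[, , 3],
      luminance = 0.2126 * image[, , 1] + 0.7152 * image[, , 2] + 0.0722 * image[, , 3],
      image[, , as.integer(channel_mode)])
  }
  stopifnot(is.matrix(image))
  if (is.null(roi)) roi <- c(0, 0, ncol(image), nrow(image))
  if (roi[3] < 1 || roi[4] < 1) stop("empty ROI")
  if (roi[1] < 0 || roi[2] < 0 || roi[1] + roi[3] > ncol(image) ||
      roi[2] + roi[4] > nrow(image)) stop("ROI outside image")
  rows <- roi[2] + seq_len(roi[4])
  cols <- roi[1] + seq_len(roi[3])
  tr <- colMeans(image[rows, cols, drop = FALSE])
  if (!is.null(background_roi)) {
    brows <- background_roi[2] + seq_len(background_roi[4])
    tr <- tr - colMeans(image[brows, cols, drop = FALSE])
  }
  tibble::tibble(pixel = cols - 1, intensity = tr)
}

#' Fit a pixel-to-wavelength calibration
#'
#' Least-squares polynomial (degree 1 or 2) through lamp-line peak positions.
#' The fitted mapping must be strictly monotonic over the valid pixel range.
#'
#' @param peak_pixels Peak positions (pixel index).
#' @param peak_wavelengths_nm Known line wavelengths (nm); pairing is
#'   order-invariant (sorted internally by pixel).
#' @param degree 1 or 2.
#' @param pixel_range Valid pixel range; defaults to the peak span.
#' @return A `ps_calibration` object with `coefficients` (ascending powers),
#'   `degree`, `residual_rms_nm`, `valid_pixel_range`.
#' @export
calibrate_wavelength <- function(peak_pixels, peak_wavelengths_nm, degree = 2,
                                 pixel_range = range(peak_pixels)) {
  stopifnot(degree %in% c(1, 2))
  if (length(peak_pixels) < degree + 1)
    stop("need at least degree + 1 peaks")
  ord <- order(peak_pixels)
  px <- peak_pixels[ord]
  wl <- sort(peak_wavelengths_nm)
  if (any(diff(px) <= 0)) stop("duplicate peak pixels")
  fit <- stats::lm(wl ~ stats::poly(px, degree, raw = TRUE))
  cf <- unname(coef(fit))
  cf[is.na(cf)] <- 0
  grid <- seq(pixel_range[1], pixel_range[2], length.out = 257)
  pred <- .poly_eval(cf, grid)
  if (!(all(diff(pred) > 0) || all(diff(pred) < 0)))
    stop("fitted mapping is not monotonic over the valid range")
  res <- wl - .poly_eval(cf, px)
  structure(list(coefficients = cf, degree = degree,
                 residual_rms_nm = sqrt(mean(res^2)),
                 valid_pixel_range = pixel_range),
            class = "ps_calibration")
}

.poly_eval <- function(cf, x) {
  out <- 0
  for (i in seq_along(cf)) out <- out + cf[i] * x^(i - 1)
  out
}

#' @export
print.ps_calibration <- function(x, ...) {
  cat(sprintf("<wavelength calibration: degree %d, rms %.3g nm, pixels [%g, %g]>\n",
              x$degree, x$residual_rms_nm, x$valid_pixel_range[1],
              x$valid_pixel_range[2]))
  invisible(x)
}

#' @export
tidy.ps_calibration <- function(x, ...) {
  tibble::tibble(term = paste0("pixel^", seq_along(x$coefficients) - 1),
                 estimate = x$coefficients)
}

#' @export
glance.ps_calibration <- function(x, ...) {
  tibble::tibble(degree = x$degree, residual_rms_nm = x$residual_rms_nm,
                 pixel_min = x$valid_pixel_range[1],
                 pixel_max = x$valid_pixel_range[2])
}

#' @export
predict.ps_calibration <- function(object, pixel, ...) {
  .poly_eval(object$coefficients, pixel)
}

#' Apply a calibration to a pixel-indexed trace
#'
#' @param trace Tibble with `pixel` and `intensity` (from
#'   [extract_spectrum()]).
#' @param calibration A `ps_calibration`.
#' @return A [spectrum_trace()] in nm, ascending.
#' @export
apply_calibration <- function(trace, calibration) {
  wl <- predict(calibration, trace$pixel)
  ord <- order(wl)
  spectrum_trace(wl[ord], trace$intensity[ord],
                 metadata = list(calibration = calibration))
}

#' Full width at half maximum of a spectral line
#'
#' Finds the local maximum nearest `peak_wavelength_nm`, subtracts a baseline
#' (the minimum intensity inside the search window), and measures the width
#' at half the baseline-subtracted peak by linear interpolation.
#'
#' @param trace A [spectrum_trace()] (or tibble with `wavelength_nm`,
#'   `intensity`).
#' @param peak_wavelength_nm Approximate line position (nm).
#' @param window_nm Half-width of the search window (nm).
#' @return FWHM in nm.
#' @export
fwhm <- function(trace, peak_wavelength_nm, window_nm = 50) {
  wl <- trace$wavelength_nm
  iy <- trace$intensity
  sel <- which(abs(wl - peak_wavelength_nm) <= window_nm)
  if (length(sel) < 5) stop("too few samples near the requested peak")
  pk <- sel[which.max(iy[sel])]
  if (pk == 1 || pk == length(wl)) stop("peak not a local maximum")
  base <- min(iy[sel])
  half <- base + (iy[pk] - base) / 2
  # walk outwards to the first crossings
  li <- pk
  while (li > 1 && iy[li] > half) li <- li - 1
  ri <- pk
  while (ri < length(wl) && iy[ri] > half) ri <- ri + 1
  if (iy[li] > half || iy[ri] > half)
    stop("half level not crossed on both sides of the peak")
  xl <- wl[li] + (half - iy[li]) / (iy[li + 1] - iy[li]) * (wl[li + 1] - wl[li])
  xr <- wl[ri - 1] + (half - iy[ri - 1]) / (iy[ri] - iy[ri - 1]) * (wl[ri] - wl[ri - 1])
  xr - xl
}

#' Transmission ratio of two spectra
#'
#' Interpolates the sample onto the reference grid over the overlapping
#' wavelength range and divides. Wavelengths where the reference falls below
#' `noise_floor` (a fraction of its maximum) are masked `NA` rather than
#' amplified. The result is relative: no absolute radiometric scale is
#' claimed.
#'
#' @param sample,reference [spectrum_trace()] objects.
#' @param noise_floor Fraction of the reference maximum below which the ratio
#'   is masked.
#' @return A [spectrum_trace()] of the ratio on the reference grid.
#' @export
transmission_ratio <- function(sample, reference, noise_floor = 0.05) {
  lo <- max(min(sample$wavelength_nm), min(reference$wavelength_nm))
  hi <- min(max(sample$wavelength_nm), max(reference$wavelength_nm))
  if (lo >= hi) stop("disjoint wavelength ranges")
  keep <- reference$wavelength_nm >= lo & reference$wavelength_nm <= hi
  wl <- reference$wavelength_nm[keep]
  refi <- reference$intensity[keep]
  smpi <- stats::approx(sample$wavelength_nm, sample$intensity, xout = wl)$y
  floor_ <- noise_floor * max(refi)
  ratio <- ifelse(refi >= floor_ & refi > 0, smpi / refi, NA_real_)
  spectrum_trace(wl, ratio, metadata = list(kind = "transmission_ratio"))
}
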