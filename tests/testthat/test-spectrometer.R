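test_that("the grating equation gives the expected diffraction angles", {
  g <- spectrometer_geometry() # 1000 lp/mm, normal incidence, first order
  expect_equal(diffraction_angle(1e-6, g), 0, tolerance = 1e-3)
  expect_equal(diffraction_angle(500, g), 30, tolerance = 1e-6)
  expect_equal(diffraction_angle(550, g), asin(0.55) * 180 / pi, tolerance = 1e-9)
  expect_error(diffraction_angle(1200, g), "evanescent")
})

test_that("slit-limited resolution matches the printed instrument and scales linearly", {
  g <- spectrometer_geometry() # 1 mm slits over 77.5 mm
  r546 <- predict_resolution(g, 546)
  expect_equal(r546, 1000 * cos(asin(0.546)) * (1 / 77.5), tolerance = 1e-9)
  expect_equal(r546, 10.81, tolerance = 1e-2)

  # halving both slits halves the resolution
  g2 <- spectrometer_geometry(entrance_slit_mm = 0.5, detector_slit_mm = 0.5)
  expect_equal(predict_resolution(g2, 546), r546 / 2, tolerance = 1e-12)

  # unequal slits: the wider one dominates
  g3 <- spectrometer_geometry(entrance_slit_mm = 0.5, detector_slit_mm = 1)
  expect_equal(predict_resolution(g3, 546), r546, tolerance = 1e-12)

  # slit width -> 0 drives resolution to 0
  g4 <- spectrometer_geometry(entrance_slit_mm = 1e-9, detector_slit_mm = 1e-9)
  expect_lt(predict_resolution(g4, 546), 1e-6)

  expect_error(spectrometer_geometry(tube_length_mm = 0), "tube")
})

test_that("d_lambda * groove_density / cos(theta_m) is wavelength-independent", {
  g <- spectrometer_geometry()
  v <- vapply(c(420, 500, 580, 650), function(wl) {
    predict_resolution(g, wl) * g$groove_density_lpmm /
      cos(diffraction_angle(wl, g) * pi / 180)
  }, numeric(1))
  expect_lt(diff(range(v)) / mean(v), 1e-12)
})

test_that("extract_spectrum averages ROI rows and is linear", {
  flat <- matrix(0.4, 60, 200)
  tr <- extract_spectrum(flat, roi = c(0, 10, 200, 30))
  expect_true(all(abs(tr$intensity - 0.4) < 1e-12))
  expect_equal(tr$pixel, 0:199)

  sc <- render_spectral_image(
    lines = data.frame(wavelength_nm = 530, amplitude = 1),
    pixel_map = c(-380 / 0.5, 2), noise_sd = 0, seed = 1)
  tr2 <- extract_spectrum(sc$image, roi = c(0, 40, 640, 40))
  expect_equal(tr2$pixel[which.max(tr2$intensity)], round(sc$truth$pixel),
               tolerance = 1)

  # linearity before clipping
  i1 <- matrix(runif(60 * 80), 60, 80)
  i2 <- matrix(runif(60 * 80), 60, 80)
  lhs <- extract_spectrum(2 * i1 + 3 * i2)$intensity
  rhs <- 2 * extract_spectrum(i1)$intensity + 3 * extract_spectrum(i2)$intensity
  expect_equal(lhs, rhs, tolerance = 1e-12)

  expect_error(extract_spectrum(flat, roi = c(0, 0, 0, 10)), "empty")
  expect_error(extract_spectrum(flat, roi = c(190, 0, 20, 10)), "outside")
})

test_that("two lines with 2:1 amplitude recover their ratio after background subtraction", {
  sc <- render_spectral_image(
    lines = data.frame(wavelength_nm = c(480, 600), amplitude = c(1, 0.5)),
    noise_sd = 0.002, seed = 7)
  tr <- extract_spectrum(sc$image, roi = c(0, 40, 640, 40),
                         background_roi = c(0, 0, 640, 10))
  p1 <- max(tr$intensity[abs(tr$pixel - sc$truth$pixel[1]) < 15])
  p2 <- max(tr$intensity[abs(tr$pixel - sc$truth$pixel[2]) < 15])
  expect_equal(p1 / p2, 2, tolerance = 0.05 * 2)
})

test_that("wavelength calibration interpolates exactly and round-trips the render", {
  # two peaks, degree 1: exact interpolation
  cal <- calibrate_wavelength(c(100, 500), c(450, 650), degree = 1)
  expect_equal(cal$residual_rms_nm, 0, tolerance = 1e-9)
  expect_equal(predict(cal, 300), 550)

  # order-invariant pairing: a decreasing wavelength list gives the same fit
  cal2 <- calibrate_wavelength(c(500, 100), c(650, 450), degree = 1)
  expect_equal(cal2$coefficients, cal$coefficients, tolerance = 1e-12)

  # frames rendered with a known quadratic mapping: 4 lamp lines recover it
  pm <- c(-760, 2.1, -5e-4)
  sc <- render_spectral_image(lines = lamp_lines(), pixel_map = pm,
                              noise_sd = 0.001, seed = 3)
  tr <- extract_spectrum(sc$image, roi = c(0, 40, 640, 40))
  pk <- find_spectral_peaks(tr, n = 4)
  cal3 <- calibrate_wavelength(pk$pixel, lamp_lines()$wavelength_nm, degree = 2)
  expect_lt(cal3$residual_rms_nm, 0.2)
  expect_equal(predict(cal3, sc$truth$pixel), sc$truth$wavelength_nm,
               tolerance = 0.3)

  expect_error(calibrate_wavelength(c(1, 2), c(400, 500), degree = 2), "peaks")
})

test_that("fwhm measures synthetic line shapes correctly", {
  # Gaussian of sigma 4.25 nm -> FWHM 2.3548 * 4.25 = 10.0 nm
  wl <- seq(500, 600, by = 0.25)
  g <- exp(-(wl - 550)^2 / (2 * 4.25^2))
  expect_equal(fwhm(spectrum_trace(wl, g), 550), 10.0, tolerance = 0.2)

  # triangle of base 2w has FWHM w
  w <- 12
  tri <- pmax(0, 1 - abs(wl - 550) / w)
  expect_equal(fwhm(spectrum_trace(wl, tri), 550), w, tolerance = 0.05)

  # a narrow rendered line reproduces the predicted slit-limited width
  sc <- render_spectral_image(
    lines = data.frame(wavelength_nm = 546, amplitude = 1, width_nm = 1e-3),
    noise_sd = 0, seed = 1)
  cal <- calibrate_wavelength(c(0, 639), c(380, 380 + 0.5 * 639), degree = 1)
  tr <- apply_calibration(extract_spectrum(sc$image, roi = c(0, 40, 640, 40)), cal)
  expect_equal(fwhm(tr, 546), predict_resolution(spectrometer_geometry(), 546),
               tolerance = 0.1 * 10.8)

  expect_error(fwhm(spectrum_trace(wl, rep(1, length(wl)) + 1e-9 * wl), 550),
               "crossed|maximum")
})

test_that("transmission ratio is exact, localises absorption bands, and masks zeros", {
  wl <- seq(450, 650, by = 1)
  ref <- spectrum_trace(wl, 1 + 0.5 * sin(wl / 40))
  expect_true(all(abs(transmission_ratio(ref, ref)$intensity - 1) < 1e-12))

  band <- 1 - 0.6 * exp(-(wl - 560)^2 / (2 * 8^2))
  smp <- spectrum_trace(wl, ref$intensity * band)
  tr <- transmission_ratio(smp, ref)
  expect_equal(tr$wavelength_nm[which.min(tr$intensity)], 560, tolerance = 1)

  ref0 <- spectrum_trace(wl, c(rep(0, 50), rep(1, length(wl) - 50)))
  tr0 <- transmission_ratio(smp, ref0, noise_floor = 0.05)
  expect_true(all(is.na(tr0$intensity[1:50])))
  expect_true(all(is.finite(tr0$intensity[60:length(wl)])))

  expect_error(transmission_ratio(spectrum_trace(1:10 + 700, rep(1, 10)),
                                  spectrum_trace(1:10 + 400, rep(1, 10))),
               "disjoint")
})

test_that("geometry and calibration files round-trip", {
  g <- spectrometer_geometry(groove_density_lpmm = 600, tube_length_mm = 50,
                             entrance_slit_mm = 0.5)
  f <- tempfile(fileext = ".yaml")
  write_geometry_yaml(g, f)
  g2 <- read_geometry_yaml(f)
  expect_equal(predict_resolution(g2, 546), predict_resolution(g, 546))

  cal <- calibrate_wavelength(c(100, 300, 500), c(450, 550, 660), degree = 2)
  fj <- tempfile(fileext = ".json")
  write_calibration_json(cal, fj)
  cal2 <- read_calibration_json(fj)
  expect_equal(predict(cal2, 200), predict(cal, 200), tolerance = 1e-10)
})
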