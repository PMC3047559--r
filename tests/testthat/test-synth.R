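test_that("Ronchi rulings have the right period, duty cycle and period count", {
  # 20 lp/mm at 5 um pixels -> 50 um = 10 px period
  r <- make_ronchi(20, 5, c(32, 100))
  expect_equal(unique(as.vector(r)), c(1, 0))
  runs <- rle(r[1, ])
  expect_true(all(runs$lengths[2:(length(runs$lengths) - 1)] == 5))
  expect_equal(mean(r), 0.5, tolerance = 0.01)
  # period count = width_px * pixel_size * lp (in mm)
  transitions <- sum(diff(r[1, ]) != 0)
  expect_equal(transitions / 2, 100 * 5e-3 * 20, tolerance = 1)
  expect_error(make_ronchi(575, 0.5), "undersampled")
})

test_that("three-bar targets have the chart geometry", {
  # 575 lp/mm at 0.2 um pixels: bar width 500/(575*0.2) = 4.35 px
  tgt <- make_three_bar_target(575, 0.2)
  expect_equal(tgt$bar_width_px, 500 / (575 * 0.2), tolerance = 1e-9)
  expect_equal(range(tgt$image), c(0, 1)) # unit contrast pre-blur
  # blurred with sigma > bar width the modulation collapses below 10%
  b <- t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(tgt$image)),
                                           sigma = 1.2 * tgt$bar_width_px)))
  # modulation read at the known bar and gap centres of the vertical triplet
  w <- tgt$bar_width_px; pad <- ceiling(3 * w)
  row_mid <- round(pad + 2.5 * w)
  bars <- round(pad + (0:2) * 2 * w + w / 2)
  gaps <- round(pad + (0:1) * 2 * w + 1.5 * w)
  i_bar <- mean(b[row_mid, bars]); i_gap <- mean(b[row_mid, gaps])
  expect_lt((i_bar - i_gap) / (i_bar + i_gap), 0.10)
  # the unblurred target has full modulation at the same probes
  expect_equal(mean(tgt$image[row_mid, bars]), 1)
  expect_equal(mean(tgt$image[row_mid, gaps]), 0)
})

test_that("smear generation is deterministic and truth-complete", {
  a <- make_blood_smear(seed = 21, shape = c(200, 200), n_cells = 25,
                        platelet_count = 5)
  b <- make_blood_smear(seed = 21, shape = c(200, 200), n_cells = 25,
                        platelet_count = 5)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
  expect_equal(sum(a$truth$type == "cell"), 25)
  expect_equal(sum(a$truth$type == "platelet"), 5)
  c2 <- make_blood_smear(seed = 22, shape = c(200, 200), n_cells = 25)
  expect_false(identical(a$image, c2$image))
})

test_that("a clean clump-free scene is counted exactly (cross-module oracle)", {
  sm <- make_blood_smear(seed = 3, n_cells = 40, clump_fraction = 0,
                         platelet_count = 0, background_ramp = 0,
                         noise_poisson_scale = 0, noise_gaussian_sd = 0,
                         shape = c(400, 400))
  expect_equal(count_smear(sm$image)$n_cells, 40)
})

test_that("aberration application is the identity for a flat focal field", {
  tex <- make_texture_scene(c(64, 64), seed = 2)
  st <- apply_aberrations(tex, aberration_spec(field_curvature_radius_mm = Inf),
                          focal_offsets_um = 0)
  expect_equal(st$frames[[1]], tex, tolerance = 1e-12)
})

test_that("field curvature moves the sharp annulus outward with focal offset", {
  tex <- make_texture_scene(c(256, 256), seed = 4)
  st <- apply_aberrations(tex, aberration_spec(), focal_offsets_um = c(0, 2))
  s0 <- sml_map(st$frames[[1]])
  s2 <- sml_map(st$frames[[2]])
  centre <- 113:144
  expect_gt(mean(s0[centre, centre]), mean(s2[centre, centre]))
  # ring where defocus(r) = 2 um: r = sqrt(2 * R * dz) = 70 um -> 152 px
  ring <- abs(sqrt(outer((1:256 - 128.5)^2, (1:256 - 128.5)^2, "+")) - 152) < 8
  expect_gt(mean(s2[ring]), mean(s0[ring]))
})

test_that("spectral scenes carry a truthful forward model", {
  # blackbody continuum peaked beyond the mapped range rises monotonically
  sc <- render_spectral_image(continuum_temperature_K = 3000, noise_sd = 0,
                              seed = 1)
  tr <- extract_spectrum(sc$image, roi = c(0, 40, 640, 40))
  sm <- stats::filter(tr$intensity, rep(1 / 33, 33))
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) > -1e-6))

  # single narrow line: rendered FWHM matches the slit model within 5%
  sc2 <- render_spectral_image(
    lines = data.frame(wavelength_nm = 546, amplitude = 1, width_nm = 1e-3),
    noise_sd = 0, seed = 1)
  expect_equal(sc2$truth$fwhm_nm, predict_resolution(spectrometer_geometry(), 546),
               tolerance = 0.05 * 10.8)

  # zero-amplitude scene: pure noise frame
  sc3 <- render_spectral_image(lines = data.frame(wavelength_nm = 546,
                                                  amplitude = 0),
                               noise_sd = 0.01, seed = 5)
  tr3 <- extract_spectrum(sc3$image, roi = c(0, 40, 640, 40))
  expect_lt(abs(mean(tr3$intensity)), 0.012)

  expect_error(render_spectral_image(
    lines = data.frame(wavelength_nm = 900, amplitude = 1)), "outside")
})

test_that("texture scenes are seeded and bounded", {
  a <- make_texture_scene(c(64, 64), seed = 8)
  expect_identical(a, make_texture_scene(c(64, 64), seed = 8))
  expect_true(all(a >= 0.1 & a <= 0.9))
  s <- make_texture_scene(c(64, 64), kind = "speckle", seed = 8)
  expect_true(all(s >= 0.1 & s <= 0.9))
  expect_error(make_texture_scene(kind = "noise"), "kind")
})
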