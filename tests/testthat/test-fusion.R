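test_that("SML is zero on constants and 4v on an isolated pixel", {
  expect_true(all(sml_map(matrix(0.37, 16, 16)) == 0))

  m <- matrix(0, 9, 9); m[5, 5] <- 0.8
  expect_equal(sml_map(m, step = 1, window = 1)[5, 5], 4 * 0.8)

  expect_error(sml_map(matrix(0, 4, 4), window = 5), "window")
  expect_error(sml_map(matrix(0, 4, 4), window = 2), "window")
})

test_that("blurring strictly lowers the mean SML of a texture", {
  tex <- smooth_texture(c(96, 96), seed = 3)
  blurred <- t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(tex)), sigma = 2)))
  expect_lt(mean(sml_map(blurred)), mean(sml_map(tex)))
})

test_that("multiscale transforms reconstruct exactly, including odd sizes", {
  set.seed(5)
  for (d in list(c(64, 64), c(37, 53))) {
    m <- matrix(runif(prod(d)), d[1], d[2])
    for (kind in c("haar", "laplacian")) {
      tr <- pocketscope:::.ms_fwd(m, levels = 3, transform = kind)
      expect_equal(pocketscope:::.ms_inv(tr), m, tolerance = 1e-12)
    }
  }
})

test_that("fusing identical frames is the identity", {
  tex <- smooth_texture(c(64, 64), seed = 9)
  for (kind in c("haar", "laplacian")) {
    fz <- fuse_multifocus(list(tex, tex), transform = kind)
    expect_equal(fz$fused, tex, tolerance = 1e-10)
  }
})

test_that("fusion of a frame with its blurred copy recovers the sharp frame", {
  tex <- smooth_texture(c(96, 96), seed = 11)
  blurred <- t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(tex)), sigma = 3)))
  fz <- fuse_multifocus(list(blurred, tex))
  rng <- diff(range(tex))
  expect_lt(mean(abs(fz$fused - tex)) / rng, 0.01)
})

test_that("fusion keeps the per-region best sharpness of half-sharp frames", {
  tex <- make_texture_scene(c(96, 96), seed = 13)
  blur <- t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(tex)), sigma = 3)))
  left_sharp <- tex; left_sharp[, 49:96] <- blur[, 49:96]
  right_sharp <- tex; right_sharp[, 1:48] <- blur[, 1:48]
  fz <- fuse_multifocus(list(left_sharp, right_sharp))
  s_f <- sml_map(fz$fused)
  s_ref <- pmax(sml_map(left_sharp), sml_map(right_sharp))
  # compare block means away from the seam
  for (cols in list(5:40, 57:92)) {
    expect_gte(mean(s_f[5:92, cols]), 0.95 * mean(s_ref[5:92, cols]))
  }
})

test_that("fusion is invariant to frame order away from SML ties", {
  tex <- make_texture_scene(c(64, 64), seed = 17)
  blur <- t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(tex)), sigma = 2)))
  a <- fuse_multifocus(list(tex, blur))$fused
  b <- fuse_multifocus(list(blur, tex))$fused
  expect_lt(mean(abs(a - b)) / diff(range(tex)), 0.002)
})

test_that("the fused image respects the input intensity envelope", {
  tex <- make_texture_scene(c(64, 64), seed = 19)
  blur <- t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(tex)), sigma = 2)))
  fz <- fuse_multifocus(list(tex, blur))
  rng <- diff(range(c(tex, blur)))
  lo <- pmin(tex, blur); hi <- pmax(tex, blur)
  expect_lte(max(fz$fused - hi), 0.02 * rng)
  expect_lte(max(lo - fz$fused), 0.02 * rng)
  expect_true(all(unlist(fz$decision) %in% 1:2))
})

test_that("frames of differing shape are rejected", {
  expect_error(fuse_multifocus(list(matrix(0, 8, 8), matrix(0, 8, 9))),
               "identical")
})

test_that("usable FOV covers the full frame of a uniformly sharp image", {
  tex <- make_texture_scene(c(128, 128), seed = 23)
  f <- usable_fov(tex, threshold = 0.5, block_px = 16)
  expect_equal(f$side_px, 128)
})

test_that("usable FOV shrinks under radial blur and grows as the threshold drops", {
  tex <- make_texture_scene(c(256, 256), seed = 29)
  st <- apply_aberrations(tex, aberration_spec(field_curvature_radius_mm = 0.3),
                          focal_offsets_um = 0)
  img <- st$frames[[1]]
  f50 <- usable_fov(img, threshold = 0.5)
  expect_lt(f50$side_px, 256)
  sides <- vapply(c(0.8, 0.5, 0.2),
                  function(th) usable_fov(img, threshold = th)$side_px,
                  numeric(1))
  expect_true(all(diff(sides) >= 0))
  expect_error(usable_fov(img, threshold = 1.2), "threshold")
})
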