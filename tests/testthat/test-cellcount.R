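# seeded disk fixtures for the segmentation/counting pipeline

disks_image <- function(centers, radius_px = 8, shape = c(340, 340),
                        depth = 0.5, bg = 0.85) {
  img <- matrix(bg, shape[1], shape[2])
  for (i in seq_len(nrow(centers))) {
    x <- centers[i, 1]; y <- centers[i, 2]
    gx <- max(1, floor(x - radius_px - 2)):min(shape[2], ceiling(x + radius_px + 2))
    gy <- max(1, floor(y - radius_px - 2)):min(shape[1], ceiling(y + radius_px + 2))
    rr <- sqrt(outer((gy - y)^2, (gx - x)^2, "+"))
    img[gy, gx] <- img[gy, gx] - depth * bg / (1 + exp((rr - radius_px) / 0.6))
  }
  pmin(pmax(img, 0), 1)
}

grid_centers <- function(n, shape = c(340, 340), spacing = 36) {
  per_row <- floor((shape[2] - 40) / spacing)
  i <- seq_len(n) - 1
  cbind(x = 30 + (i %% per_row) * spacing,
        y = 30 + (i %/% per_row) * spacing)
}

test_that("a blank image yields zero labels, not an error", {
  params <- counting_params()
  labs <- segment_cells(matrix(0.8, 120, 120), params)
  expect_equal(labs$n, 0)
  res <- count_cells(labs, params)
  expect_equal(res$n_cells, 0)
})

test_that("well-separated disks are counted exactly", {
  n <- 50
  img <- disks_image(grid_centers(n))
  params <- counting_params(pixel_size_um = 0.46)
  labs <- segment_cells(img, params)
  expect_equal(labs$n, n)
  expect_equal(count_cells(labs, params, image = img)$n_cells, n)
})

test_that("watershed splits a pair of disks overlapping by 30% of a radius", {
  r <- 9
  centers <- rbind(c(120, 150), c(120 + 1.7 * r, 150))
  img <- disks_image(centers, radius_px = r)
  params <- counting_params(pixel_size_um = 0.46)
  labs <- segment_cells(img, params)
  expect_equal(labs$n, 2)
  # split conserves area: children tile the foreground mask
  expect_equal(sum(tabulate(labs$labels[labs$labels > 0])),
               sum(labs$labels > 0))
  res <- count_cells(labs, params)
  expect_equal(res$n_cells, 2)
  expect_lt(abs(res$records$area_um2[1] - res$records$area_um2[2]) /
              mean(res$records$area_um2), 0.35)
})

test_that("platelet-scale specks are rejected by the area filter", {
  big <- grid_centers(40)
  small <- grid_centers(12) + 17
  img <- disks_image(big, radius_px = 8)
  img2 <- disks_image(small, radius_px = 2.2, bg = 1)
  img <- img + (img2 - 1) # superimpose the small absorbers
  params <- counting_params(min_area_um2 = 20, pixel_size_um = 0.46)
  res <- count_cells(segment_cells(img, params), params)
  expect_equal(res$n_cells, 40)
  expect_gte(res$rejected["too_small"], 10)
})

test_that("raising min_area never increases the count", {
  sm <- make_blood_smear(seed = 5, shape = c(400, 400), n_cells = 60)
  corr <- correct_background(sm$image)
  labs <- segment_cells(corr)
  counts <- vapply(c(5, 20, 40, 60), function(a) {
    count_cells(labs, counting_params(min_area_um2 = a))$n_cells
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("background correction flattens an illumination ramp", {
  sm <- make_blood_smear(seed = 9, shape = c(400, 400), n_cells = 60,
                         background_ramp = 0.3, noise_poisson_scale = 0,
                         noise_gaussian_sd = 0)
  # plane fit over background pixels only (cells masked via ground truth)
  cells <- sm$truth[sm$truth$type == "cell", ]
  bgmask <- matrix(TRUE, nrow(sm$image), ncol(sm$image))
  for (i in seq_len(nrow(cells))) {
    r <- ceiling(cells$radius_um[i] / 0.46) + 3
    ys <- max(1, round(cells$y_px[i]) - r):min(400, round(cells$y_px[i]) + r)
    xs <- max(1, round(cells$x_px[i]) - r):min(400, round(cells$x_px[i]) + r)
    bgmask[ys, xs] <- FALSE
  }
  tilt <- function(img) {
    df <- data.frame(v = as.vector(img),
                     x = as.vector(col(img)) / ncol(img),
                     y = as.vector(row(img)) / nrow(img))[as.vector(bgmask), ]
    cf <- coef(stats::lm(v ~ x + y, data = df))
    sqrt(cf["x"]^2 + cf["y"]^2)
  }
  for (method in c("morphological", "polynomial")) {
    corr <- correct_background(sm$image, method = method)
    expect_lt(tilt(corr), 0.05 * tilt(sm$image))
    # mean-preserving and polarity-preserving: cells stay darker than background
    expect_equal(mean(corr), mean(sm$image), tolerance = 1e-6)
    cells <- sm$truth[sm$truth$type == "cell", ]
    idx <- cbind(round(cells$y_px) + 1, round(cells$x_px) + 1)
    expect_lt(mean(corr[idx]), mean(corr))
  }
  expect_error(correct_background(matrix(0, 40, 40), struct_px = 41), "larger")
})

test_that("counts are invariant to intensity scaling and 90-degree rotation", {
  sm <- make_blood_smear(seed = 13, shape = c(400, 400), n_cells = 60)
  n0 <- count_smear(sm$image)$n_cells
  expect_equal(count_smear(sm$image * 0.6)$n_cells, n0)
  rot <- t(sm$image)[, nrow(sm$image):1]
  expect_equal(count_smear(rot)$n_cells, n0)
})

test_that("the standard smear protocol is counted to the accuracy bar", {
  acc <- vapply(1:5, function(sd) {
    sm <- make_blood_smear(seed = sd)
    truth <- sum(sm$truth$type == "cell")
    100 * (1 - abs(count_smear(sm$image)$n_cells - truth) / truth)
  }, numeric(1))
  expect_gte(median(acc), 97)
})
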