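# Seeded synthetic-fixture generators: resolution targets, blood smears,
# field-curvature/pincushion-degraded focal stacks and dispersed slit images.
# All generators are pure functions of (spec, seed): byte-identical reruns.

#' Ronchi ruling image
#'
#' Binary square-wave grating (vertical bars) of a given spatial frequency at
#' the object plane.
#'
#' @param lp_per_mm Ruling frequency (line pairs per mm).
#' @param pixel_size_um Object-plane pixel size (um/px).
#' @param shape `c(height, width)` in px.
#' @param phase Phase offset in periods.
#' @return Matrix of 0/1 values; a full period must span >= 4 px.
#' @examples
#' r <- make_ronchi(20, 5, c(64, 100)) # 10 px period
#' @export
make_ronchi <- function(lp_per_mm, pixel_size_um, shape = c(256, 256), phase = 0) {
  period_px <- 1000 / (lp_per_mm * pixel_size_um)
  if (period_px < 4) stop("undersampled ruling: period below 4 px")
  x <- seq_len(shape[2]) - 1
  bar <- as.numeric((((x / period_px) + phase) %% 1) < 0.5)
  matrix(rep(bar, each = shape[1]), shape[1], shape[2])
}

#' Three-bar resolution element
#'
#' Standard three-bar target geometry (5:1 bar aspect) at one spatial
#' frequency: a horizontal triplet and its orthogonal copy, unit contrast on
#' a zero background.
#'
#' @inheritParams make_ronchi
#' @return List: `image` matrix, `bar_width_px`.
#' @export
make_three_bar_target <- function(lp_per_mm, pixel_size_um) {
  w <- 500 / (lp_per_mm * pixel_size_um) # bar width in px (half period)
  if (2 * w < 4) stop("undersampled target: period below 4 px")
  len <- 5 * w
  pad <- ceiling(3 * w)
  H <- ceiling(len + 3 * pad + 5 * w)
  W <- ceiling(len + 2 * pad)
  img <- matrix(0, H, W)
  fill_bar <- function(img, y0, y1, x0, x1) {
    ys <- max(1, ceiling(y0 + 1)):min(H, floor(y1))
    xs <- max(1, ceiling(x0 + 1)):min(W, floor(x1))
    img[ys, xs] <- 1
    img
  }
  # vertical bars (resolve horizontal frequency)
  for (i in 0:2) {
    x0 <- pad + i * 2 * w
    img <- fill_bar(img, pad, pad + len, x0, x0 + w)
  }
  # horizontal triplet below
  y_base <- pad + len + pad
  for (i in 0:2) {
    y0 <- y_base + i * 2 * w
    img <- fill_bar(img, y0, y0 + w, pad, pad + len)
  }
  list(image = img, bar_width_px = w)
}

#' Synthetic blood smear with ground truth
#'
#' Renders absorbing red cells (annulus profile with central pallor) on a
#' bright background with an illumination ramp, overlapping clumped pairs,
#' platelet-scale dark specks, Poisson shot noise, Gaussian read noise and
#' 8-bit quantisation. Reproducible for a fixed seed.
#'
#' @param n_cells Number of red cells.
#' @param clump_fraction Fraction of cells placed as overlapping pairs.
#' @param cell_radius_mean_um,cell_radius_sd_um Cell radius distribution (um).
#' @param platelet_count Platelet-scale distractors.
#' @param background_ramp Fractional illumination gradient across the field.
#' @param noise_poisson_scale Photons at unit intensity (0 disables).
#' @param noise_gaussian_sd Additive read-noise sd (0 disables).
#' @param pixel_size_um Object-plane pixel size (um/px).
#' @param shape `c(height, width)` px.
#' @param seed Integer seed.
#' @return List: `image` matrix in [0, 1], `truth` tibble (`type`, `x_px`,
#'   `y_px` 0-based centres, `radius_um`, `clump_id`), and the evaluated
#'   `spec` list.
#' @export
make_blood_smear <- function(n_cells = 115, clump_fraction = 0.10,
                             cell_radius_mean_um = 3.8, cell_radius_sd_um = 0.3,
                             platelet_count = 15,
                             background_ramp = 0.15,
                             noise_poisson_scale = 200,
                             noise_gaussian_sd = 0.005,
                             pixel_size_um = 0.46,
                             shape = c(600, 600), seed = 1) {
  stopifnot(n_cells >= 0, clump_fraction >= 0, clump_fraction <= 1,
            platelet_count >= 0)
  spec <- list(n_cells = n_cells, clump_fraction = clump_fraction,
               cell_radius_mean_um = cell_radius_mean_um,
               cell_radius_sd_um = cell_radius_sd_um,
               platelet_count = platelet_count,
               background_ramp = background_ramp,
               noise_poisson_scale = noise_poisson_scale,
               noise_gaussian_sd = noise_gaussian_sd,
               pixel_size_um = pixel_size_um, shape = shape, seed = seed)
  withr::with_seed(seed, {
    H <- shape[1]; W <- shape[2]
    rpx <- function(r_um) r_um / pixel_size_um
    n_pair_cells <- 2 * floor(n_cells * clump_fraction / 2)
    n_single <- n_cells - n_pair_cells

    placed <- data.frame(x = numeric(0), y = numeric(0), r = numeric(0),
                         clump = integer(0))
    margin <- rpx(cell_radius_mean_um) + 3
    ok_dist <- function(x, y, r, min_fac) {
      if (!nrow(placed)) return(TRUE)
      d <- sqrt((placed$x - x)^2 + (placed$y - y)^2)
      all(d >= min_fac * (placed$r + r))
    }
    tries <- 0; budget <- 400 * max(1, n_cells)
    add_one <- function(r, clump_id, min_fac = 0.95) {
      repeat {
        tries <<- tries + 1
        if (tries > budget) stop("cannot place cells within overlap budget")
        x <- runif(1, margin, W - margin)
        y <- runif(1, margin, H - margin)
        if (ok_dist(x, y, r, min_fac)) {
          placed[nrow(placed) + 1, ] <<- list(x, y, r, clump_id)
          return(c(x, y))
        }
      }
    }
    clump_id <- 0L
    for (i in seq_len(n_pair_cells / 2)) {
      clump_id <- clump_id + 1L
      r1 <- max(1, rnorm(1, rpx(cell_radius_mean_um), rpx(cell_radius_sd_um)))
      r2 <- max(1, rnorm(1, rpx(cell_radius_mean_um), rpx(cell_radius_sd_um)))
      p <- add_one(r1, clump_id)
      # partner overlapping by ~30% of a radius
      repeat {
        tries <- tries + 1
        if (tries > budget) stop("cannot place cells within overlap budget")
        ang <- runif(1, 0, 2 * pi)
        dd <- 0.85 * (r1 + r2)
        x2 <- p[1] + dd * cos(ang); y2 <- p[2] + dd * sin(ang)
        if (x2 > margin && x2 < W - margin && y2 > margin && y2 < H - margin) {
          others <- placed[placed$clump != clump_id | placed$clump == 0, ]
          d <- if (nrow(others)) sqrt((others$x - x2)^2 + (others$y - y2)^2) else Inf
          if (all(d >= 0.95 * (others$r + r2))) {
            placed[nrow(placed) + 1, ] <- list(x2, y2, r2, clump_id)
            break
          }
        }
      }
    }
    for (i in seq_len(n_single)) {
      r <- max(1, rnorm(1, rpx(cell_radius_mean_um), rpx(cell_radius_sd_um)))
      add_one(r, 0L)
    }
    plat <- data.frame(x = runif(platelet_count, margin, W - margin),
                       y = runif(platelet_count, margin, H - margin),
                       r = rpx(1.1) * runif(platelet_count, 0.8, 1.2))

    # render: bright background with linear ramp, multiplicative absorption
    xs <- matrix(rep(seq_len(W) - 1, each = H), H, W)
    ys <- matrix(rep(seq_len(H) - 1, W), H, W)
    bg <- 0.85 * (1 + background_ramp * ((xs - W / 2) / W + 0.3 * (ys - H / 2) / H))
    absorb <- matrix(0, H, W)
    stamp <- function(absorb, x, y, r, a_edge, a_center, soft = 1.2) {
      x0 <- max(1, floor(x - r - 3)); x1 <- min(W, ceiling(x + r + 3))
      y0 <- max(1, floor(y - r - 3)); y1 <- min(H, ceiling(y + r + 3))
      gx <- x0:x1; gy <- y0:y1
      rr <- sqrt(outer((gy - 1 - y)^2, (gx - 1 - x)^2, "+"))
      sup <- 1 / (1 + exp((rr - r) / (soft / 2)))
      prof <- a_edge * exp(-((rr - 0.72 * r) / (0.30 * r))^2) +
              a_center * exp(-(rr / (0.5 * r))^2)
      absorb[gy, gx] <- absorb[gy, gx] + prof * sup
      absorb
    }
    for (i in seq_len(nrow(placed)))
      absorb <- stamp(absorb, placed$x[i], placed$y[i], placed$r[i], 0.45, 0.12)
    for (i in seq_len(nrow(plat)))
      absorb <- stamp(absorb, plat$x[i], plat$y[i], plat$r[i], 0.25, 0.55, soft = 0.8)
    img <- bg * exp(-absorb)

    if (noise_poisson_scale > 0)
      img <- matrix(rpois(length(img), img * noise_poisson_scale) /
                      noise_poisson_scale, H, W)
    if (noise_gaussian_sd > 0)
      img <- img + matrix(rnorm(length(img), 0, noise_gaussian_sd), H, W)
    img <- pmin(pmax(img, 0), 1)
    img <- round(img * 255) / 255

    truth <- tibble::tibble(
      type = c(rep("cell", nrow(placed)), rep("platelet", nrow(plat))),
      x_px = c(placed$x, plat$x), y_px = c(placed$y, plat$y),
      radius_um = c(placed$r, plat$r) * pixel_size_um,
      clump_id = c(ifelse(placed$clump == 0, NA_integer_, placed$clump),
                   rep(NA_integer_, nrow(plat))))
    list(image = img, truth = truth, spec = spec)
  })
}

#' Field-curvature aberration description
#'
#' The surface of best focus is a sphere of radius `field_curvature_radius_mm`
#' (defocus grows as `r^2 / 2R` with object-plane field radius `r`), so a
#' frame recorded at focal offset `dz` is sharp on the annulus where the
#' sphere crosses `dz`. Blur is converted geometrically: the defocus disc of
#' radius `NA * dz` becomes a Gaussian with the same rms radius,
#' `sigma = NA * dz / sqrt(2)`, expressed per object-plane pixel — the
#' default ties the fixture to the simulated instrument (NA 0.479, 2.2 um
#' pixels demagnified by 4.8).
#'
#' @param field_curvature_radius_mm Radius of the focal sphere (mm); `Inf`
#'   disables field curvature.
#' @param blur_px_per_um Blur growth per um of defocus (px/um).
#' @param distortion Optional `ps_distortion` applied after blurring.
#' @param pixel_size_um Object-plane pixel size (um/px).
#' @return An `ps_aberration` list.
#' @export
aberration_spec <- function(field_curvature_radius_mm = 1.1,
                            blur_px_per_um = 0.479 / (sqrt(2) * 0.458),
                            distortion = NULL,
                            pixel_size_um = 0.458) {
  stopifnot(field_curvature_radius_mm > 0, blur_px_per_um >= 0)
  structure(list(field_curvature_radius_mm = field_curvature_radius_mm,
                 blur_px_per_um = blur_px_per_um,
                 distortion = distortion, pixel_size_um = pixel_size_um),
            class = "ps_aberration")
}

#' Apply field-curvature defocus and distortion to a scene
#'
#' Produces one frame per focal offset: per-pixel Gaussian blur with
#' `sigma(r) = blur_px_per_um * |dz(r) - offset|`, `dz(r) = r^2 / 2R`,
#' followed by the optional radial warp. Variable blur is realised by
#' blending a bank of uniformly blurred copies (linear interpolation in
#' sigma).
#'
#' @param image Grayscale matrix (the in-focus scene).
#' @param spec An [aberration_spec()].
#' @param focal_offsets_um Focal offsets (um) at which frames are rendered;
#'   the default `c(0, 2)` mimics recording a second frame with the sample
#'   plane translated 2 um towards the phone.
#' @param n_sigma_levels Size of the blur bank.
#' @return An image stack: list with `frames` (list of matrices) and
#'   `focal_offsets_um`.
#' @export
apply_aberrations <- function(image, spec = aberration_spec(),
                              focal_offsets_um = c(0, 2),
                              n_sigma_levels = 9) {
  stopifnot(is.matrix(image), inherits(spec, "ps_aberration"))
  H <- nrow(image); W <- ncol(image)
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  xs <- matrix(rep(seq_len(W) - 1, each = H), H, W)
  ys <- matrix(rep(seq_len(H) - 1, W), H, W)
  r_mm <- sqrt((xs - cx)^2 + (ys - cy)^2) * spec$pixel_size_um / 1000
  dz_um <- if (is.finite(spec$field_curvature_radius_mm))
    r_mm^2 / (2 * spec$field_curvature_radius_mm) * 1000 else 0 * r_mm

  frames <- lapply(focal_offsets_um, function(off) {
    sig <- spec$blur_px_per_um * abs(dz_um - off)
    smax <- min(max(sig), 15)
    sig <- pmin(sig, smax)
    if (smax < 1e-3) {
      out <- image
    } else {
      levels <- seq(0, smax, length.out = n_sigma_levels)
      bank <- lapply(levels, function(s) {
        if (s < 1e-3) image else
          t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(image)), sigma = s)))
      })
      idx <- pmin(findInterval(sig, levels), n_sigma_levels - 1)
      frac <- (sig - levels[idx]) / diff(levels)[1]
      out <- matrix(0, H, W)
      for (k in seq_len(n_sigma_levels - 1)) {
        sel <- idx == k
        if (!any(sel)) next
        out[sel] <- bank[[k]][sel] * (1 - frac[sel]) + bank[[k + 1]][sel] * frac[sel]
      }
      top <- sig >= levels[n_sigma_levels]
      out[top] <- bank[[n_sigma_levels]][top]
    }
    if (!is.null(spec$distortion)) out <- distort(out, spec$distortion)
    out
  })
  list(frames = frames, focal_offsets_um = focal_offsets_um, spec = spec)
}

# Planck spectral radiance, arbitrary units, lambda in nm
.planck <- function(lambda_nm, T_K) {
  l <- lambda_nm * 1e-9
  (l^-5) / (exp(1.43877688e-2 / (l * T_K)) - 1)
}

#' Render a dispersed slit image with ground truth
#'
#' Emulates the camera frame of the slit-grating spectrometer: each emission
#' line is placed at its mapped pixel column and broadened by the two-slit
#' triangular acceptance (FWHM from [predict_resolution()]) convolved with a
#' Gaussian intrinsic width; an optional blackbody continuum is added with
#' the mapping Jacobian. Rows inside the slit-height band carry signal,
#' leaving dark margins usable for background subtraction.
#'
#' @param lines Data frame with `wavelength_nm`, `amplitude`, and optional
#'   `width_nm` (intrinsic FWHM, default 0.5).
#' @param geometry A [spectrometer_geometry()].
#' @param pixel_map Polynomial coefficients (ascending powers) mapping nm to
#'   pixel column; must place every line inside the frame.
#' @param continuum_temperature_K Optional blackbody temperature.
#' @param continuum_amplitude Peak continuum intensity.
#' @param shape `c(height, width)` px.
#' @param noise_sd Additive Gaussian noise sd (0 disables).
#' @param seed Integer seed.
#' @return List: `image` matrix, `truth` tibble (`wavelength_nm`, `pixel`,
#'   `fwhm_nm` of the rendered noiseless profile), `wavelength_of_pixel`
#'   (length-width vector), `spec`.
#' @export
render_spectral_image <- function(lines = NULL,
                                  geometry = spectrometer_geometry(),
                                  pixel_map = c(-380 / 0.5, 1 / 0.5),
                                  continuum_temperature_K = NULL,
                                  continuum_amplitude = 0.3,
                                  shape = c(120, 640),
                                  noise_sd = 0.003, seed = 1) {
  H <- shape[1]; W <- shape[2]
  # invert the nm -> px map on a dense grid
  wl_grid <- seq(200, 1200, by = 0.05)
  px_grid <- .poly_eval(pixel_map, wl_grid)
  if (any(diff(px_grid) <= 0) && any(diff(px_grid) >= 0) &&
      !(all(diff(px_grid) > 0) || all(diff(px_grid) < 0)))
    stop("pixel map must be monotonic")
  wl_of_px <- stats::approx(px_grid, wl_grid, xout = seq_len(W) - 1, rule = 1)$y
  if (anyNA(wl_of_px)) {
    # frame extends beyond the mapped range; fill by linear extension
    ok <- !is.na(wl_of_px)
    fit <- stats::lm(wl ~ px, data = data.frame(wl = wl_of_px[ok],
                                                px = (seq_len(W) - 1)[ok]))
    wl_of_px[!ok] <- predict(fit, newdata = data.frame(px = (seq_len(W) - 1)[!ok]))
  }

  row_profile <- numeric(W)
  truth <- NULL
  if (!is.null(lines) && nrow(as.data.frame(lines))) {
    lines <- as.data.frame(lines)
    if (is.null(lines$width_nm)) lines$width_nm <- 0.5
    for (i in seq_len(nrow(lines))) {
      l0 <- lines$wavelength_nm[i]
      px0 <- .poly_eval(pixel_map, l0)
      if (px0 < 0 || px0 > W - 1) stop("line outside mapped pixel range")
      res_nm <- predict_resolution(geometry, l0)
      sg <- max(lines$width_nm[i], 1e-6) / 2.3548
      # triangular slit acceptance (base 2*res) (x) Gaussian intrinsic
      # width, in closed form: the tent's second derivative is three deltas,
      # so conv(tent, gauss)(x) = [g2(x+a) - 2 g2(x) + g2(x-a)] / a with
      # g2(x) = x Phi(x/sigma) + sigma^2 phi_sigma(x) (exact for any width)
      tent_gauss <- function(x, a, s) {
        g2 <- function(z) z * stats::pnorm(z / s) + s * stats::dnorm(z / s)
        (g2(x + a) - 2 * g2(x) + g2(x - a)) / a
      }
      dl <- wl_of_px - l0
      prof <- tent_gauss(dl, res_nm, sg)
      prof <- prof / tent_gauss(0, res_nm, sg)
      row_profile <- row_profile + lines$amplitude[i] * prof
      # numeric FWHM of the rendered noiseless line
      fine <- seq(-3 * res_nm, 3 * res_nm, by = 0.005)
      pf <- tent_gauss(fine, res_nm, sg)
      above <- fine[pf >= max(pf) / 2]
      truth <- rbind(truth,
                     data.frame(wavelength_nm = l0, pixel = px0,
                                fwhm_nm = diff(range(above))))
    }
  }
  if (!is.null(continuum_temperature_K)) {
    jac <- abs(c(diff(wl_of_px), diff(wl_of_px)[W - 1]))
    bb <- .planck(wl_of_px, continuum_temperature_K) * jac
    row_profile <- row_profile + continuum_amplitude * bb / max(bb)
  }

  rows <- seq_len(H)
  band <- 1 / (1 + exp(-(rows - 0.25 * H) / 2)) * 1 / (1 + exp((rows - 0.75 * H) / 2))
  img <- outer(band, row_profile)
  img <- withr::with_seed(seed, {
    if (noise_sd > 0) img <- img + matrix(rnorm(length(img), 0, noise_sd), H, W)
    img
  })
  img <- pmin(pmax(img, 0), 1)
  img <- round(img * 255) / 255
  list(image = img,
       truth = if (is.null(truth)) tibble::tibble(wavelength_nm = numeric(),
                                                  pixel = numeric(),
                                                  fwhm_nm = numeric())
               else tibble::as_tibble(truth),
       wavelength_of_pixel = wl_of_px,
       spec = list(geometry = geometry, pixel_map = pixel_map,
                   continuum_temperature_K = continuum_temperature_K,
                   shape = shape, noise_sd = noise_sd, seed = seed))
}

#' Default fluorescent-lamp line list for calibration fixtures
#'
#' Mercury/europium lines at 405, 436, 546 and 611 nm.
#'
#' @return Tibble with `wavelength_nm`, `amplitude`.
#' @export
lamp_lines <- function() {
  tibble::tibble(wavelength_nm = c(405, 436, 546, 611),
                 amplitude = c(0.5, 0.9, 1.0, 0.8))
}

#' Seeded texture scene for focus-metric protocols
#'
#' Two flavours of spatially uniform texture. `"grid"` (default) is a fine
#' crossed sinusoidal grating with seed-randomised phases: deterministic
#' local contrast everywhere, so the block-wise focus metric responds to
#' blur only -- the fixture of choice for usable-field-of-view measurements.
#' `"speckle"` is a smooth Gaussian random field (white noise low-pass
#' filtered to a correlation length), a generic natural-texture stand-in.
#'
#' @param shape `c(height, width)` px.
#' @param kind `"grid"` or `"speckle"`.
#' @param period_px Grating period for `"grid"` (px).
#' @param correlation_px Gaussian correlation length for `"speckle"` (px).
#' @param seed Integer seed.
#' @return Matrix in [0.1, 0.9].
#' @export
make_texture_scene <- function(shape = c(512, 512), kind = "grid",
                               period_px = 6, correlation_px = 1.5,
                               seed = 1) {
  withr::with_seed(seed, {
    if (kind == "grid") {
      ph <- runif(2, 0, 2 * pi)
      x <- outer(rep(1, shape[1]), seq_len(shape[2]) - 1)
      y <- outer(seq_len(shape[1]) - 1, rep(1, shape[2]))
      m <- sin(2 * pi * x / period_px + ph[1]) *
           sin(2 * pi * y / period_px + ph[2])
      0.5 + 0.4 * m
    } else if (kind == "speckle") {
      m <- matrix(rnorm(prod(shape)), shape[1], shape[2])
      m <- t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(m)),
                                               sigma = correlation_px)))
      m <- (m - min(m)) / (max(m) - min(m))
      0.1 + 0.8 * m
    } else stop("unknown texture kind: ", kind)
  })
}
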