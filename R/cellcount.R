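# Marker-controlled watershed counting of red cells in smear images.
# Pipeline: background correction -> global threshold -> hole filling and
# light cleanup -> distance transform -> watershed seeded at h-maxima of the
# distance map (touching cells split) -> area-filtered morphometrics.

#' Counting parameters
#'
#' @param min_area_um2,max_area_um2 Acceptance band for object area at the
#'   object plane; defaults bracket the ~50 um2 projected area of a red cell
#'   and exclude platelet-scale debris.
#' @param pixel_size_um Object-plane pixel size (um/px).
#' @param h_maxima_depth Watershed marker depth as a fraction of the distance
#'   map maximum; maxima shallower than this merge (prevents over-splitting).
#' @param threshold_method `"otsu"` only, kept as a tag for extension.
#' @param background_correction `"morphological"` or `"polynomial"`.
#' @param cell_polarity `"dark"` for absorbing cells on a bright background,
#'   `"bright"` for the inverse.
#' @param smooth_sigma_px Pre-threshold Gaussian smoothing (px; 0 disables).
#' @return A `ps_count_params` object.
#' @export
counting_params <- function(min_area_um2 = 20, max_area_um2 = 150,
                            pixel_size_um = 0.46,
                            h_maxima_depth = 0.1,
                            threshold_method = "otsu",
                            background_correction = "morphological",
                            cell_polarity = "dark",
                            smooth_sigma_px = 1) {
  stopifnot(min_area_um2 > 0, min_area_um2 < max_area_um2, pixel_size_um > 0,
            h_maxima_depth > 0, h_maxima_depth < 1)
  structure(list(min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
                 pixel_size_um = pixel_size_um, h_maxima_depth = h_maxima_depth,
                 threshold_method = threshold_method,
                 background_correction = background_correction,
                 cell_polarity = cell_polarity,
                 smooth_sigma_px = smooth_sigma_px),
            class = "ps_count_params")
}

#' Remove large-scale illumination background
#'
#' Estimates the background with a grayscale morphological closing (dark
#' objects) or opening (bright objects) using a structuring element much
#' larger than a cell, or with a quadratic polynomial surface fit, and
#' subtracts it. The output keeps the input mean, so contrast polarity is
#' preserved.
#'
#' @param image Grayscale matrix.
#' @param struct_px Structuring element diameter (odd, px); must be smaller
#'   than the image.
#' @param method `"morphological"` or `"polynomial"`.
#' @param cell_polarity `"dark"` or `"bright"`.
#' @return Corrected matrix (same mean as input).
#' @export
correct_background <- function(image, struct_px = 61,
                               method = "morphological",
                               cell_polarity = "dark") {
  stopifnot(is.matrix(image))
  if (struct_px >= min(dim(image))) stop("structuring element larger than image")
  if (method == "morphological") {
    w <- if (struct_px %% 2 == 0) struct_px + 1 else struct_px
    br <- EBImage::makeBrush(w, shape = "disc")
    # reflect-pad by the brush radius so border pixels see a full window
    k <- (w - 1) / 2
    pad <- image[c(k:1, seq_len(nrow(image)), nrow(image) - 0:(k - 1)),
                 c(k:1, seq_len(ncol(image)), ncol(image) - 0:(k - 1))]
    im <- EBImage::Image(t(pad))
    bg <- if (cell_polarity == "dark") EBImage::closing(im, br)
          else EBImage::opening(im, br)
    bg <- t(EBImage::imageData(bg))[k + seq_len(nrow(image)),
                                    k + seq_len(ncol(image))]
  } else if (method == "polynomial") {
    nr <- nrow(image); nc <- ncol(image)
    yy <- (row(image) - nr / 2) / nr
    xx <- (col(image) - nc / 2) / nc
    df <- data.frame(v = as.vector(image), x = as.vector(xx), y = as.vector(yy))
    sub <- df[seq(1, nrow(df), by = max(1, floor(nrow(df) / 40000))), ]
    # fit the surface on likely-background pixels only (cells are the dark /
    # bright minority, so restrict to the appropriate intensity half)
    sub <- if (cell_polarity == "dark")
      sub[sub$v >= stats::quantile(sub$v, 0.45), ]
    else sub[sub$v <= stats::quantile(sub$v, 0.55), ]
    fit <- stats::lm(v ~ x + y + I(x^2) + I(y^2) + I(x * y), data = sub)
    bg <- matrix(predict(fit, newdata = df), nr, nc)
  } else stop("unknown background method: ", method)
  image - bg + mean(bg)
}

#' Segment cells by marker-controlled watershed
#'
#' Global Otsu threshold of the (background-corrected) image, hole filling,
#' light morphological cleanup, then a watershed of the foreground distance
#' transform whose markers are distance-map maxima deeper than
#' `h_maxima_depth * max(distance)` — touching cells are split along the
#' distance-map ridges.
#'
#' @param image Grayscale matrix (ideally from [correct_background()]).
#' @param params A [counting_params()].
#' @return A `ps_labels` object: integer `labels` matrix (0 = background,
#'   labels contiguous 1..N), `n`, and the `params` used.
#' @export
segment_cells <- function(image, params = counting_params()) {
  stopifnot(is.matrix(image), inherits(params, "ps_count_params"))
  fg <- if (params$cell_polarity == "dark") max(image) - image else image
  im <- EBImage::Image(t(fg))
  if (params$smooth_sigma_px > 0)
    im <- EBImage::gblur(im, sigma = params$smooth_sigma_px)
  rng <- range(im)
  if (diff(rng) < 1e-12) {
    lab <- matrix(0L, nrow(image), ncol(image))
    return(structure(list(labels = lab, n = 0L, params = params),
                     class = "ps_labels"))
  }
  thr <- EBImage::otsu(im, range = rng)
  mask <- im > thr
  mask <- EBImage::fillHull(mask)
  mask <- EBImage::opening(mask, EBImage::makeBrush(3, "diamond"))
  if (sum(mask) == 0) {
    lab <- matrix(0L, nrow(image), ncol(image))
    return(structure(list(labels = lab, n = 0L, params = params),
                     class = "ps_labels"))
  }
  dm <- EBImage::distmap(mask)
  tol <- params$h_maxima_depth * max(dm)
  ws <- EBImage::watershed(dm, tolerance = tol, ext = 1)
  lab <- t(EBImage::imageData(ws))
  # relabel contiguously
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) && !identical(ids, seq_along(ids))) {
    remap <- integer(max(ids))
    remap[ids] <- seq_along(ids)
    lab[lab > 0] <- remap[lab[lab > 0]]
  }
  structure(list(labels = matrix(as.integer(lab), nrow(lab)),
                 n = length(ids), params = params),
            class = "ps_labels")
}

#' @export
print.ps_labels <- function(x, ...) {
  cat(sprintf("<segmentation: %d labels in %dx%d image>\n",
              x$n, nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Count cells from a segmentation
#'
#' Size-filters the labelled regions to the `[min_area, max_area]` band
#' (platelet-scale specks fall below, fused clumps above) and reports
#' per-cell morphometrics.
#'
#' @param labels A `ps_labels` from [segment_cells()].
#' @param params A [counting_params()]; defaults to the one used for
#'   segmentation.
#' @param image Optional intensity image for `mean_intensity`.
#' @return A `ps_count` object: `n_cells`, `records` (tibble: label, centroid
#'   x/y in 0-based px, `area_um2`, `eccentricity`, `mean_intensity`),
#'   `rejected` (named counts by reason).
#' @export
count_cells <- function(labels, params = labels$params, image = NULL) {
  stopifnot(inherits(labels, "ps_labels"))
  lab <- labels$labels
  n <- labels$n
  if (n == 0) {
    return(structure(list(n_cells = 0L,
                          records = tibble::tibble(label = integer(), x_px = numeric(),
                                                   y_px = numeric(), area_um2 = numeric(),
                                                   eccentricity = numeric(),
                                                   mean_intensity = numeric()),
                          rejected = c(too_small = 0L, too_large = 0L)),
                     class = "ps_count"))
  }
  px_area <- params$pixel_size_um^2
  idx <- which(lab > 0)
  l <- lab[idx]
  ys <- (idx - 1) %% nrow(lab)        # 0-based row
  xs <- (idx - 1) %/% nrow(lab)       # 0-based col
  area_px <- tabulate(l, n)
  cx <- tapply(xs, l, mean)
  cy <- tapply(ys, l, mean)
  # eccentricity from central second moments
  ecc <- vapply(seq_len(n), function(i) {
    sel <- l == i
    dx <- xs[sel] - cx[[i]]; dy <- ys[sel] - cy[[i]]
    mxx <- mean(dx^2); myy <- mean(dy^2); mxy <- mean(dx * dy)
    tr <- mxx + myy; dt <- sqrt(max(0, (mxx - myy)^2 + 4 * mxy^2))
    l1 <- (tr + dt) / 2; l2 <- (tr - dt) / 2
    if (l1 <= 0) 0 else sqrt(max(0, 1 - l2 / l1))
  }, numeric(1))
  mi <- if (is.null(image)) rep(NA_real_, n) else
    as.numeric(tapply(image[idx], l, mean))
  area_um2 <- area_px * px_area
  keep <- area_um2 >= params$min_area_um2 & area_um2 <= params$max_area_um2
  rec <- tibble::tibble(label = seq_len(n), x_px = as.numeric(cx),
                        y_px = as.numeric(cy), area_um2 = area_um2,
                        eccentricity = ecc, mean_intensity = mi)[keep, ]
  structure(list(
    n_cells = sum(keep),
    records = rec,
    rejected = c(too_small = sum(area_um2 < params$min_area_um2),
                 too_large = sum(area_um2 > params$max_area_um2))
  ), class = "ps_count")
}

#' @export
print.ps_count <- function(x, ...) {
  cat(sprintf("<cell count: %d cells (%d too small, %d too large rejected)>\n",
              x$n_cells, x$rejected["too_small"], x$rejected["too_large"]))
  invisible(x)
}

#' @export
glance.ps_count <- function(x, ...) {
  tibble::tibble(n_cells = x$n_cells,
                 rejected_too_small = unname(x$rejected["too_small"]),
                 rejected_too_large = unname(x$rejected["too_large"]),
                 mean_area_um2 = mean(x$records$area_um2),
                 mean_eccentricity = mean(x$records$eccentricity))
}

#' @export
tidy.ps_count <- function(x, ...) x$records

#' @export
autoplot.ps_count <- function(object, ...) {
  ggplot2::ggplot(object$records,
                  ggplot2::aes(x = .data$x_px, y = .data$y_px,
                               size = .data$area_um2)) +
    ggplot2::geom_point(alpha = 0.6, colour = "firebrick") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)", size = "area (um2)",
                  title = sprintf("%d cells", object$n_cells))
}

#' Count cells in a smear image (one-call pipeline)
#'
#' Convenience wrapper: background correction, segmentation and counting in
#' one step.
#'
#' @param image Grayscale matrix.
#' @param params A [counting_params()].
#' @return A `ps_count`.
#' @export
count_smear <- function(image, params = counting_params()) {
  corr <- correct_background(image,
                             method = params$background_correction,
                             cell_polarity = params$cell_polarity)
  count_cells(segment_cells(corr, params), params, image = image)
}

#' Overlay segmentation on an image (Fig.-7-style shaded mask)
#'
#' @param image Grayscale matrix in [0, 1].
#' @param labels A `ps_labels`.
#' @param col Overlay colour weights (RGB).
#' @return `height x width x 3` RGB array.
#' @export
overlay_labels <- function(image, labels, col = c(1, 0.2, 0.2)) {
  m <- (labels$labels > 0) * 0.5
  arr <- array(0, c(nrow(image), ncol(image), 3))
  for (ch in 1:3) arr[, , ch] <- pmin(1, image * (1 - m) + m * col[ch])
  arr
}
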