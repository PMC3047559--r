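# Radial (pincushion/barrel) distortion: fitting from point correspondences
# and image resampling. Normalised-radius convention: with r~ = r / r_norm,
# r_distorted = r_ideal * (1 + k1 r~^2 + k2 r~^4); k1 > 0 is pincushion.

#' Radial distortion model
#'
#' @param center Length-2 distortion centre in pixel coordinates (0-based,
#'   x = column, y = row).
#' @param k1,k2 Radial coefficients under the normalised-radius convention.
#' @param r_norm Normalising radius in pixels.
#' @return A `ps_distortion` object.
#' @export
radial_distortion_model <- function(center, k1, k2 = 0, r_norm = 1) {
  stopifnot(length(center) == 2, r_norm > 0)
  structure(list(center = as.numeric(center), k1 = k1, k2 = k2,
                 r_norm = r_norm, residual_rms_px = NA_real_),
            class = "ps_distortion")
}

#' @export
print.ps_distortion <- function(x, ...) {
  cat(sprintf("<radial distortion: center (%.2f, %.2f), k1=%.4g, k2=%.4g, r_norm=%.1f px%s>\n",
              x$center[1], x$center[2], x$k1, x$k2, x$r_norm,
              if (is.na(x$residual_rms_px)) "" else
                sprintf(", fit rms %.3f px", x$residual_rms_px)))
  invisible(x)
}

#' @export
tidy.ps_distortion <- function(x, ...) {
  tibble::tibble(term = c("center_x", "center_y", "k1", "k2"),
                 estimate = c(x$center, x$k1, x$k2))
}

#' @export
glance.ps_distortion <- function(x, ...) {
  tibble::tibble(k1 = x$k1, k2 = x$k2, r_norm_px = x$r_norm,
                 residual_rms_px = x$residual_rms_px)
}

# ideal -> distorted (forward model), points as n x 2 (x, y)
.distort_points <- function(pts, model) {
  d <- sweep(pts, 2, model$center)
  r <- sqrt(rowSums(d^2))
  rt <- r / model$r_norm
  f <- 1 + model$k1 * rt^2 + model$k2 * rt^4
  sweep(d * f, 2, model$center, "+")
}

# distorted -> ideal: invert the scalar radial map by Newton iteration
.undistort_points <- function(pts, model) {
  d <- sweep(pts, 2, model$center)
  rd <- sqrt(rowSums(d^2))
  ri <- rd
  for (i in 1:25) {
    rt <- ri / model$r_norm
    f <- 1 + model$k1 * rt^2 + model$k2 * rt^4
    g <- ri * f - rd
    dg <- 1 + 3 * model$k1 * rt^2 + 5 * model$k2 * rt^4
    ri <- ri - g / dg
  }
  scale <- ifelse(rd > 0, ri / rd, 1)
  sweep(d * scale, 2, model$center, "+")
}

#' Fit a radial distortion model from grid correspondences
#'
#' Least-squares fit of the normalised radial polynomial
#' `r_d = r_i (1 + k1 r~^2 + k2 r~^4)` together with the distortion centre,
#' from observed (distorted) and ideal point pairs. Positive fitted `k1`
#' indicates pincushion, negative barrel.
#'
#' @param observed,ideal Data frames or matrices with columns `x`, `y`
#'   (pixels); at least 12 correspondences spanning the field.
#' @param r_norm Normalising radius (px); default half the ideal point
#'   bounding-box diagonal.
#' @return A `ps_distortion` with `residual_rms_px` filled in.
#' @export
fit_pincushion <- function(observed, ideal, r_norm = NULL) {
  obs <- as.matrix(as.data.frame(observed)[, c("x", "y")])
  idl <- as.matrix(as.data.frame(ideal)[, c("x", "y")])
  stopifnot(nrow(obs) == nrow(idl))
  if (nrow(obs) < 12) stop("need at least 12 correspondences")
  sp <- apply(idl, 2, function(v) diff(range(v)))
  ev <- eigen(stats::cov(idl), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-6 * max(ev)) stop("degenerate correspondences (collinear)")
  if (is.null(r_norm)) r_norm <- sqrt(sum(sp^2)) / 2
  cen0 <- colMeans(idl)
  span <- sqrt(sum(sp^2))
  if (span < 0.2 * r_norm) stop("correspondences do not span the field")

  solve_k <- function(cen) {
    di <- sweep(idl, 2, cen)
    do <- sweep(obs, 2, cen)
    ri <- sqrt(rowSums(di^2))
    rt <- ri / r_norm
    # residuals of both coordinates: do = di * (1 + k1 rt^2 + k2 rt^4)
    A <- rbind(di[, 1] * rt^2, di[, 2] * rt^2)
    B <- rbind(di[, 1] * rt^4, di[, 2] * rt^4)
    y <- c(do[, 1] - di[, 1], do[, 2] - di[, 2])
    X <- cbind(c(A[1, ], A[2, ]), c(B[1, ], B[2, ]))
    k <- tryCatch(solve(crossprod(X), crossprod(X, y)), error = function(e) c(0, 0))
    res <- y - X %*% k
    list(k = as.numeric(k), sse = sum(res^2))
  }
  obj <- function(cen) solve_k(cen)$sse
  opt <- stats::optim(cen0, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 500))
  cen <- opt$par
  kk <- solve_k(cen)
  m <- radial_distortion_model(cen, kk$k[1], kk$k[2], r_norm)
  m$residual_rms_px <- sqrt(kk$sse / (2 * nrow(obs)))
  m
}

# bilinear sample of matrix `img` at (x, y) pixel coords (0-based), n x 2
.bilinear <- function(img, xy) {
  nr <- nrow(img); nc <- ncol(img)
  x <- pmin(pmax(xy[, 1], 0), nc - 1)
  y <- pmin(pmax(xy[, 2], 0), nr - 1)
  x0 <- pmin(floor(x), nc - 2); y0 <- pmin(floor(y), nr - 2)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0 + 1, x0 + 1)
  v00 <- img[i00]
  v01 <- img[cbind(y0 + 1, x0 + 2)]
  v10 <- img[cbind(y0 + 2, x0 + 1)]
  v11 <- img[cbind(y0 + 2, x0 + 2)]
  v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
    v10 * (1 - fx) * fy + v11 * fx * fy
}

#' Undistort / distort an image under a radial model
#'
#' `undistort()` resamples so that the output is the ideal (distortion-free)
#' image: each output pixel is looked up at its forward-mapped distorted
#' position with bilinear interpolation. `distort()` applies the distortion
#' (used by the synthetic generators), inverting the radial map by Newton
#' iteration.
#'
#' @param image Grayscale matrix.
#' @param model A `ps_distortion`.
#' @return Resampled matrix of the same shape.
#' @export
undistort <- function(image, model) {
  stopifnot(is.matrix(image), inherits(model, "ps_distortion"))
  g <- expand.grid(x = seq_len(ncol(image)) - 1, y = seq_len(nrow(image)) - 1)
  src <- .distort_points(as.matrix(g), model)
  matrix(.bilinear(image, src), nrow(image), ncol(image), byrow = TRUE)
}

#' @rdname undistort
#' @export
distort <- function(image, model) {
  stopifnot(is.matrix(image), inherits(model, "ps_distortion"))
  g <- expand.grid(x = seq_len(ncol(image)) - 1, y = seq_len(nrow(image)) - 1)
  src <- .undistort_points(as.matrix(g), model)
  matrix(.bilinear(image, src), nrow(image), ncol(image), byrow = TRUE)
}
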