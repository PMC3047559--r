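# Multifocus fusion: sum-modified-Laplacian focus metric, a pluggable
# multiscale transform (separable Haar wavelet default, Laplacian pyramid
# alternative), per-coefficient max-SML decision map with majority-vote
# consistency smoothing.

# shift matrix by (dy, dx) with reflective border
.shift_reflect <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- seq_len(nr) - dy
  ci <- seq_len(nc) - dx
  ri <- ifelse(ri < 1, 1 - ri + 1, ifelse(ri > nr, 2 * nr - ri, ri))
  ci <- ifelse(ci < 1, 1 - ci + 1, ifelse(ci > nc, 2 * nc - ci, ci))
  m[ri, ci, drop = FALSE]
}

# box-sum filter of odd width w via cumulative sums on a reflected pad
.box_sum <- function(m, w) {
  if (w == 1) return(m)
  k <- (w - 1) / 2
  out <- matrix(0, nrow(m), ncol(m))
  for (dy in -k:k) for (dx in -k:k) out <- out + .shift_reflect(m, dy, dx)
  out
}

#' Sum-modified-Laplacian focus map
#'
#' The modified Laplacian at a pixel is
#' `|2 I(x,y) - I(x-s,y) - I(x+s,y)| + |2 I(x,y) - I(x,y-s) - I(x,y+s)|`;
#' the SML sums it over a `window x window` neighbourhood. Large where the
#' image is locally sharp, identically zero on a constant image. Borders are
#' handled by reflection.
#'
#' @param image Numeric matrix (grayscale image).
#' @param step Second-difference step `s` in pixels (>= 1).
#' @param window Odd summation window width (>= 1).
#' @return Matrix of SML values (same shape, >= 0).
#' @examples
#' m <- matrix(0, 9, 9); m[5, 5] <- 1
#' sml_map(m, window = 1)[5, 5] # 4
#' @export
sml_map <- function(image, step = 1, window = 3) {
  stopifnot(is.matrix(image), step >= 1, window >= 1, window %% 2 == 1)
  if (window > min(dim(image))) stop("window larger than image")
  s <- as.integer(step)
  ml <- abs(2 * image - .shift_reflect(image, 0, -s) - .shift_reflect(image, 0, s)) +
        abs(2 * image - .shift_reflect(image, -s, 0) - .shift_reflect(image, s, 0))
  .box_sum(ml, window)
}

# ---- separable Haar wavelet -------------------------------------------------

.haar_step <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  o <- seq(1, nr, by = 2); e <- o + 1
  L <- (m[o, , drop = FALSE] + m[e, , drop = FALSE]) / sqrt(2)
  H <- (m[o, , drop = FALSE] - m[e, , drop = FALSE]) / sqrt(2)
  oc <- seq(1, nc, by = 2); ec <- oc + 1
  list(LL = (L[, oc, drop = FALSE] + L[, ec, drop = FALSE]) / sqrt(2),
       LH = (L[, oc, drop = FALSE] - L[, ec, drop = FALSE]) / sqrt(2),
       HL = (H[, oc, drop = FALSE] + H[, ec, drop = FALSE]) / sqrt(2),
       HH = (H[, oc, drop = FALSE] - H[, ec, drop = FALSE]) / sqrt(2))
}

.haar_unstep <- function(b) {
  L <- matrix(0, nrow(b$LL), 2 * ncol(b$LL))
  H <- matrix(0, nrow(b$LL), 2 * ncol(b$LL))
  oc <- seq(1, ncol(L), by = 2); ec <- oc + 1
  L[, oc] <- (b$LL + b$LH) / sqrt(2); L[, ec] <- (b$LL - b$LH) / sqrt(2)
  H[, oc] <- (b$HL + b$HH) / sqrt(2); H[, ec] <- (b$HL - b$HH) / sqrt(2)
  m <- matrix(0, 2 * nrow(L), ncol(L))
  o <- seq(1, nrow(m), by = 2); e <- o + 1
  m[o, ] <- (L + H) / sqrt(2)
  m[e, ] <- (L - H) / sqrt(2)
  m
}

.pad_reflect <- function(m, nr, nc) {
  if (nrow(m) < nr) {
    extra <- nr - nrow(m)
    m <- rbind(m, m[nrow(m) - seq_len(extra) + 1, , drop = FALSE])
  }
  if (ncol(m) < nc) {
    extra <- nc - ncol(m)
    m <- cbind(m, m[, ncol(m) - seq_len(extra) + 1, drop = FALSE])
  }
  m
}

.haar_fwd <- function(m, levels) {
  d0 <- dim(m)
  mult <- 2^levels
  m <- .pad_reflect(m, ceiling(nrow(m) / mult) * mult, ceiling(ncol(m) / mult) * mult)
  bands <- vector("list", levels)
  for (l in seq_len(levels)) {
    st <- .haar_step(m)
    bands[[l]] <- st[c("LH", "HL", "HH")]
    m <- st$LL
  }
  list(kind = "haar", levels = levels, orig_dim = d0, bands = bands, LL = m)
}

.haar_inv <- function(tr) {
  m <- tr$LL
  for (l in rev(seq_len(tr$levels)))
    m <- .haar_unstep(c(list(LL = m), tr$bands[[l]]))
  m[seq_len(tr$orig_dim[1]), seq_len(tr$orig_dim[2]), drop = FALSE]
}

# ---- Laplacian pyramid ------------------------------------------------------

.down2 <- function(m) {
  o <- seq(1, nrow(m), by = 2); oc <- seq(1, ncol(m), by = 2)
  (m[o, oc, drop = FALSE] + m[o + 1, oc, drop = FALSE] +
   m[o, oc + 1, drop = FALSE] + m[o + 1, oc + 1, drop = FALSE]) / 4
}

.up2 <- function(m) {
  m[rep(seq_len(nrow(m)), each = 2), rep(seq_len(ncol(m)), each = 2), drop = FALSE]
}

.lappyr_fwd <- function(m, levels) {
  d0 <- dim(m)
  mult <- 2^levels
  m <- .pad_reflect(m, ceiling(nrow(m) / mult) * mult, ceiling(ncol(m) / mult) * mult)
  bands <- vector("list", levels)
  for (l in seq_len(levels)) {
    g <- .down2(m)
    bands[[l]] <- list(D = m - .up2(g))
    m <- g
  }
  list(kind = "laplacian", levels = levels, orig_dim = d0, bands = bands, LL = m)
}

.lappyr_inv <- function(tr) {
  m <- tr$LL
  for (l in rev(seq_len(tr$levels)))
    m <- .up2(m) + tr$bands[[l]]$D
  m[seq_len(tr$orig_dim[1]), seq_len(tr$orig_dim[2]), drop = FALSE]
}

.ms_fwd <- function(m, levels, transform) {
  switch(transform, haar = .haar_fwd(m, levels),
         laplacian = .lappyr_fwd(m, levels),
         stop("unknown transform: ", transform))
}

.ms_inv <- function(tr) {
  switch(tr$kind, haar = .haar_inv(tr), laplacian = .lappyr_inv(tr))
}

# single-pass 3x3 majority vote on an integer decision map
.majority3 <- function(dm, n_frames) {
  votes <- lapply(seq_len(n_frames), function(i) .box_sum((dm == i) * 1, 3))
  out <- matrix(1L, nrow(dm), ncol(dm))
  best <- votes[[1]]
  for (i in seq_len(n_frames)[-1]) {
    better <- votes[[i]] > best
    out[better] <- i
    best[better] <- votes[[i]][better]
  }
  out
}

#' Fuse a multifocus image stack
#'
#' Each frame is decomposed with a multiscale transform; every coefficient is
#' taken from the frame whose coefficients are locally sharpest by the
#' sum-modified Laplacian, after a single-pass 3x3 majority-vote smoothing of
#' the per-band decision maps (ties go to the lowest frame index). The inverse
#' transform of the composite yields the fused image, clipped to the input
#' intensity envelope.
#'
#' @param frames List of >= 2 co-registered grayscale matrices of identical
#'   shape (a single frame is returned unchanged).
#' @param levels Transform depth (>= 1).
#' @param window SML window (odd).
#' @param transform `"haar"` (separable wavelet, default) or `"laplacian"`
#'   (Laplacian pyramid).
#' @return A `ps_fusion` object: `fused` matrix, `decision` (per-band integer
#'   winner maps), `decision_pixel` (image-domain SML winner map, a
#'   convenience view), `levels`, `transform`.
#' @export
fuse_multifocus <- function(frames, levels = 3, window = 3, transform = "haar") {
  stopifnot(is.list(frames), length(frames) >= 1, levels >= 1)
  dims <- lapply(frames, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    stop("frames must have identical shapes")
  n <- length(frames)
  lo <- min(vapply(frames, min, numeric(1)))
  hi <- max(vapply(frames, max, numeric(1)))
  trs <- lapply(frames, .ms_fwd, levels = levels, transform = transform)

  pick <- function(mats) {
    sml <- lapply(mats, sml_map, step = 1, window = window)
    win <- matrix(1L, nrow(mats[[1]]), ncol(mats[[1]]))
    best <- sml[[1]]
    for (i in seq_len(n)[-1]) {
      better <- sml[[i]] > best
      win[better] <- i
      best[better] <- sml[[i]][better]
    }
    win <- .majority3(win, n)
    out <- mats[[1]]
    for (i in seq_len(n)[-1]) out[win == i] <- mats[[i]][win == i]
    list(m = out, win = win)
  }

  fused <- trs[[1]]
  decision <- list()
  band_names <- names(trs[[1]]$bands[[1]])
  for (l in seq_len(levels)) {
    for (bn in band_names) {
      pk <- pick(lapply(trs, function(t) t$bands[[l]][[bn]]))
      fused$bands[[l]][[bn]] <- pk$m
      decision[[paste0("L", l, "_", bn)]] <- pk$win
    }
  }
  pk <- pick(lapply(trs, function(t) t$LL))
  fused$LL <- pk$m
  decision[["LL"]] <- pk$win

  img <- .ms_inv(fused)
  img[img < lo] <- lo
  img[img > hi] <- hi

  pkx <- pick(frames)
  structure(list(fused = img, decision = decision, decision_pixel = pkx$win,
                 levels = levels, transform = transform),
            class = "ps_fusion")
}

#' @export
print.ps_fusion <- function(x, ...) {
  cat(sprintf("<multifocus fusion: %dx%d image, %s transform, %d levels>\n",
              nrow(x$fused), ncol(x$fused), x$transform, x$levels))
  invisible(x)
}

#' Usable field of view of an image
#'
#' Aggregates the SML focus map into `block_px` blocks and finds the largest
#' centred square in which every block reaches at least
#' `threshold * max(block SML)`. With the object-plane pixel size the extent
#' is also reported in micrometres.
#'
#' @param image Grayscale matrix.
#' @param threshold Sharpness fraction in (0, 1).
#' @param block_px Block size for SML aggregation (pixels).
#' @param pixel_size_um Object-plane pixel size (um), optional.
#' @return One-row tibble: `side_px`, `area_px2`, `side_um`, `area_um2`
#'   (`NA` without a pixel size), `peak_block_sml`.
#' @export
usable_fov <- function(image, threshold = 0.5, block_px = 16,
                       pixel_size_um = NULL) {
  stopifnot(is.matrix(image))
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  s <- sml_map(image)
  nbr <- floor(nrow(s) / block_px)
  nbc <- floor(ncol(s) / block_px)
  if (nbr < 1 || nbc < 1) stop("image smaller than one block")
  blocks <- matrix(0, nbr, nbc)
  for (i in seq_len(nbr)) for (j in seq_len(nbc))
    blocks[i, j] <- mean(s[(i - 1) * block_px + seq_len(block_px),
                           (j - 1) * block_px + seq_len(block_px)])
  peak <- max(blocks)
  ok <- blocks >= threshold * peak
  bmax <- min(nbr, nbc)
  side_blocks <- 0
  for (b in seq_len(bmax)) {
    r0 <- floor((nbr - b) / 2)
    c0 <- floor((nbc - b) / 2)
    if (all(ok[r0 + seq_len(b), c0 + seq_len(b)])) side_blocks <- b else break
  }
  side_px <- side_blocks * block_px
  tibble::tibble(
    side_px = side_px,
    area_px2 = side_px^2,
    side_um = if (is.null(pixel_size_um)) NA_real_ else side_px * pixel_size_um,
    area_um2 = if (is.null(pixel_size_um)) NA_real_ else (side_px * pixel_size_um)^2,
    peak_block_sml = peak
  )
}
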