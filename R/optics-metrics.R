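#' Point-source fan model
#'
#' Describes the pencil of rays leaving one object point: its field height and
#' the divergence half-angle of the cone, sampled by a deterministic
#' concentric-ring fan (no RNG, so every metric is bit-reproducible). The
#' default 5 degree divergence models weakly divergent trans-illumination,
#' the regime the instrument is used in: each object point is imaged through
#' the illumination pencil, not the full lens aperture.
#'
#' @param field_height_mm Radial object-plane position of the point (mm).
#' @param divergence_half_angle_deg Cone half-angle (degrees, >= 0).
#' @param n_rays Requested number of rays (>= 50 for spot metrics).
#' @return A `ps_source` object.
#' @export
source_model <- function(field_height_mm = 0, divergence_half_angle_deg = 5,
                         n_rays = 200) {
  stopifnot(divergence_half_angle_deg >= 0, n_rays >= 1)
  n_az <- 8
  structure(list(field_height_mm = field_height_mm,
                 divergence_half_angle_deg = divergence_half_angle_deg,
                 n_rings = max(1L, ceiling((n_rays - 1) / n_az)),
                 n_az = n_az),
            class = "ps_source")
}

.source_fan <- function(source, object_z) {
  .ring_fan(c(0, source$field_height_mm, object_z),
            sin(source$divergence_half_angle_deg * pi / 180),
            n_rings = source$n_rings, n_az = source$n_az)
}

#' Spot diagram on the sensor
#'
#' Traces a deterministic ring fan from one object point and collects the
#' surviving sensor-plane intersections.
#'
#' @param train A `ps_train`.
#' @param source A [source_model()] supplying at least 50 rays.
#' @param object_z Object plane; defaults to the train's.
#' @return A `ps_spot` object: `hits` (tibble of sensor x/y in mm),
#'   `rms_radius_mm` (about the centroid of surviving rays), `centroid_mm`,
#'   `n_launched`, `n_vignetted`.
#' @export
spot_metrics <- function(train, source = source_model(), object_z = train$object_z) {
  fan <- .source_fan(source, object_z)
  n <- nrow(fan$O)
  if (n < 50) stop("spot metrics need at least 50 rays")
  tb <- .trace_bundle(train, fan$O, fan$D)
  if (!any(tb$alive)) stop("no throughput: all rays vignetted")
  H <- tb$hits[tb$alive, , drop = FALSE]
  cen <- colMeans(H)
  rms <- sqrt(mean((H[, 1] - cen[1])^2 + (H[, 2] - cen[2])^2))
  structure(list(
    hits = tibble::tibble(x_mm = H[, 1], y_mm = H[, 2]),
    rms_radius_mm = rms,
    centroid_mm = cen,
    n_launched = n,
    n_vignetted = sum(!tb$alive),
    reasons = table(tb$reason[!tb$alive])
  ), class = "ps_spot")
}

#' @export
print.ps_spot <- function(x, ...) {
  cat(sprintf("<spot diagram: %d/%d rays, rms %.3f um, centroid (%.4f, %.4f) mm>\n",
              nrow(x$hits), x$n_launched, x$rms_radius_mm * 1000,
              x$centroid_mm[1], x$centroid_mm[2]))
  invisible(x)
}

#' @export
autoplot.ps_spot <- function(object, ...) {
  ggplot2::ggplot(object$hits, ggplot2::aes(x = .data$x_mm, y = .data$y_mm)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "sensor x (mm)", y = "sensor y (mm)",
                  title = sprintf("Spot diagram (rms %.2f um)",
                                  object$rms_radius_mm * 1000))
}

.spot_rms <- function(train, object_z, source) {
  fan <- .source_fan(source, object_z)
  tb <- .trace_bundle(train, fan$O, fan$D)
  if (!any(tb$alive)) return(NA_real_)
  H <- tb$hits[tb$alive, , drop = FALSE]
  cen <- colMeans(H)
  sqrt(mean((H[, 1] - cen[1])^2 + (H[, 2] - cen[2])^2))
}

#' Locate the plane of best focus
#'
#' Minimises the on-axis sensor-plane rms spot radius over the object
#' distance, using the deterministic source fan.
#'
#' @param train A `ps_train`.
#' @param search_range Length-2 interval of object z (mm) bracketing the
#'   minimum; defaults to the train's object plane +/- 30 percent.
#' @param source A [source_model()].
#' @param tol_mm Search tolerance (mm); default 0.1 um.
#' @return Best-focus object z (mm, negative).
#' @export
find_best_focus <- function(train, search_range = NULL,
                            source = source_model(), tol_mm = 1e-4) {
  if (is.null(search_range))
    search_range <- sort(train$object_z * c(1.3, 0.7))
  f <- function(z) {
    r <- .spot_rms(train, z, source)
    if (is.na(r)) Inf else r
  }
  opt <- stats::optimize(f, interval = search_range, tol = tol_mm)
  span <- diff(search_range)
  if (min(abs(opt$minimum - search_range)) < 2 * max(tol_mm, 1e-3 * span))
    stop("no interior rms minimum in search range")
  opt$minimum
}

# Paraxial element heights per unit object-side tan(theta) for an on-axis
# point: trace an infinitesimal-angle real ray and record the intersection
# height at every element.
.paraxial_heights <- function(train, object_z, eps = 1e-6) {
  rs <- .rays(c(0, 0, object_z), c(eps, 0, 1))
  h <- numeric(length(train$elements))
  for (i in seq_along(train$elements)) {
    rs <- .through_element(rs, train$elements[[i]])
    if (!rs$alive[1]) {
      h[i:length(h)] <- NA
      break
    }
    h[i] <- rs$O[1, 1]
  }
  h / eps
}

#' Numerical aperture of the train
#'
#' First-order (paraxial marginal-ray) NA: the sine of the half-angle of the
#' widest paraxial cone from the on-axis object point that clears every
#' element aperture. This is the conventional quoted NA; real marginal rays
#' of a heavily aberrated ball lens can sneak past the stop at larger angles,
#' which is reported separately by [spot_metrics()] vignetting counts.
#'
#' @param train A `ps_train`.
#' @param object_z Object plane (mm); defaults to the train's.
#' @return NA (dimensionless sine).
#' @export
numerical_aperture <- function(train, object_z = train$object_z) {
  hpt <- .paraxial_heights(train, object_z)
  aps <- vapply(train$elements, `[[`, numeric(1), "aperture_radius")
  tans <- aps / abs(hpt)
  tan_max <- min(tans, na.rm = TRUE)
  if (!is.finite(tan_max)) stop("cannot determine limiting aperture")
  sin(atan(tan_max))
}

# index of the paraxially limiting aperture (the stop)
.stop_index <- function(train, object_z) {
  hpt <- .paraxial_heights(train, object_z)
  aps <- vapply(train$elements, `[[`, numeric(1), "aperture_radius")
  which.min(aps / abs(hpt))
}

# y-height at element k for a ray launched from `origin` with slope sy
.height_at <- function(train, origin, sy, k) {
  d <- c(0, sy, sqrt(max(0, 1 - sy^2)))
  rs <- .rays(origin, d)
  for (i in seq_len(k)) {
    rs <- .through_element(rs, train$elements[[i]])
    if (!rs$alive[1]) return(NA_real_)
  }
  rs$O[1, 2]
}

# chief-ray magnification: aim a ray from field height h through the centre
# of the aperture stop, read its sensor height
.chief_magnification <- function(train, object_z, h = 0.05) {
  k <- .stop_index(train, object_z)
  org <- c(0, h, object_z)
  f <- function(sy) .height_at(train, org, sy, k)
  grid <- seq(-0.75, 0.75, length.out = 61)
  vals <- vapply(grid, f, numeric(1))
  okv <- which(!is.na(vals))
  if (length(okv) < 2) stop("chief ray not found")
  sgn <- sign(vals[okv])
  flip <- which(diff(sgn) != 0)
  if (!length(flip)) stop("chief ray not found")
  lo <- grid[okv[flip[1]]]; hi <- grid[okv[flip[1] + 1]]
  flo <- f(lo)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (is.na(fm)) { hi <- mid; next }
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  sy <- (lo + hi) / 2
  tb <- .trace_bundle(train, matrix(org, 1), matrix(c(0, sy, sqrt(1 - sy^2)), 1))
  if (!tb$alive[1]) stop("chief ray vignetted")
  abs(tb$hits[1, 2] / h)
}

.centroid_magnification <- function(train, object_z, source, h = 0.05) {
  src <- source
  src$field_height_mm <- h
  fan <- .source_fan(src, object_z)
  tb <- .trace_bundle(train, fan$O, fan$D)
  if (!any(tb$alive)) return(NA_real_)
  abs(mean(tb$hits[tb$alive, 2]) / h)
}

# largest field diameter with >= 50% fan throughput
.vignetting_fov <- function(train, object_z, source, max_h) {
  frac <- function(h) {
    src <- source
    src$field_height_mm <- h
    fan <- .source_fan(src, object_z)
    mean(.trace_bundle(train, fan$O, fan$D)$alive)
  }
  if (frac(max_h) >= 0.5) return(2 * max_h)
  lo <- 0; hi <- max_h
  for (i in 1:30) {
    mid <- (lo + hi) / 2
    if (frac(mid) >= 0.5) lo <- mid else hi <- mid
  }
  2 * lo
}

#' First-order system metrics of an imaging train
#'
#' Locates best focus, then reports magnification (chief-ray and centroid
#' definitions), object-plane field of view, numerical aperture, depth of
#' field and the Rayleigh resolution 0.61 lambda / NA.
#'
#' Depth of field is the sensor-referred geometric estimate
#' `2 * sqrt(2) * p / (M * NA)` — the axial object range over which the
#' first-order defocus blur contributes no more than one pixel pitch `p` of
#' rms spot growth — with the diffraction estimate `lambda / NA^2` reported
#' alongside.
#'
#' @param train A `ps_train`.
#' @param wavelength_nm Evaluation wavelength for the diffraction figures.
#' @param source A [source_model()] used for best focus and centroids.
#' @param best_focus Optional precomputed best-focus object z (mm); computed
#'   with [find_best_focus()] when `NULL`.
#' @return A one-row tibble: `magnification`, `magnification_centroid`,
#'   `field_of_view_diameter_mm`, `best_focus_object_distance_mm` (unsigned
#'   distance from z = 0, i.e. the ball centre for the default train),
#'   `depth_of_field_um`, `depth_of_field_diffraction_um`,
#'   `numerical_aperture`, `rayleigh_resolution_um`, `wavelength_nm`,
#'   `rms_spot_um`.
#' @examples
#' \donttest{
#' system_metrics(build_iphone2g_microscope(), wavelength_nm = 488)
#' }
#' @export
system_metrics <- function(train, wavelength_nm = 550,
                           source = source_model(), best_focus = NULL) {
  if (is.null(best_focus)) best_focus <- find_best_focus(train, source = source)
  na_ <- numerical_aperture(train, best_focus)
  M <- .chief_magnification(train, best_focus)
  Mc <- .centroid_magnification(train, best_focus, source)
  sens_fov <- min(train$sensor$width_mm, train$sensor$height_mm) / M
  vig_fov <- .vignetting_fov(train, best_focus, source, max_h = sens_fov)
  fov <- min(sens_fov, vig_fov)
  p_mm <- train$sensor$pixel_pitch_um / 1000
  dof_pix <- 2 * sqrt(2) * p_mm / (M * na_) * 1000
  dof_diff <- (wavelength_nm * 1e-3) / na_^2
  rms <- .spot_rms(train, best_focus, source)
  tibble::tibble(
    magnification = M,
    magnification_centroid = Mc,
    field_of_view_diameter_mm = fov,
    best_focus_object_distance_mm = abs(best_focus),
    depth_of_field_um = dof_pix,
    depth_of_field_diffraction_um = dof_diff,
    numerical_aperture = na_,
    rayleigh_resolution_um = 0.61 * wavelength_nm * 1e-3 / na_,
    wavelength_nm = wavelength_nm,
    rms_spot_um = rms * 1000
  )
}

#' USAF-1951 element spatial frequency
#'
#' The chart defines `2^(group + (element - 1) / 6)` line pairs per mm.
#'
#' @param group Chart group (integer, may be negative).
#' @param element Element within the group, 1 to 6.
#' @return Frequency in line pairs per mm.
#' @examples
#' usaf_frequency(9, 2) # 574.7 lp/mm
#' @export
usaf_frequency <- function(group, element) {
  stopifnot(group == round(group))
  if (any(element != round(element)) || any(element < 1) || any(element > 6))
    stop("element must be an integer in 1..6")
  2^(group + (element - 1) / 6)
}
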