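# Vectorised sequential ray tracing. Rays are row-wise: O (n x 3 origins),
# D (n x 3 unit directions), alive (logical), reason (why dead).

.rays <- function(O, D) {
  O <- matrix(O, ncol = 3)
  D <- matrix(D, ncol = 3)
  D <- D / sqrt(rowSums(D^2))
  list(O = O, D = D, alive = rep(TRUE, nrow(O)),
       reason = rep(NA_character_, nrow(O)))
}

.kill <- function(rs, idx, why) {
  hit <- rs$alive & idx
  rs$alive[hit] <- FALSE
  rs$reason[hit] <- why
  rs
}

# Snell refraction of direction rows D at unit normals N (oriented against D),
# eta = n_before / n_after. Returns list(D, tir): tir rows are invalid.
.snell <- function(D, N, eta) {
  ci <- -rowSums(D * N)
  s2 <- eta^2 * (1 - ci^2)
  tir <- s2 > 1
  ct <- sqrt(pmax(0, 1 - s2))
  Dn <- eta * D + (eta * ci - ct) * N
  Dn <- Dn / sqrt(rowSums(Dn^2))
  list(D = Dn, tir = tir)
}

# Propagate live rays through one element; updates O, D, alive, reason.
.through_element <- function(rs, e) {
  a <- rs$alive
  if (!any(a)) return(rs)
  O <- rs$O[a, , drop = FALSE]
  D <- rs$D[a, , drop = FALSE]

  if (e$type == "sphere" && e$curvature_radius != 0) {
    R <- e$curvature_radius
    C <- c(0, 0, e$vertex_z + R)
    OC <- sweep(O, 2, C)
    b <- rowSums(OC * D)
    c0 <- rowSums(OC^2) - R^2
    disc <- b^2 - c0
    miss <- disc < 0
    s <- sqrt(pmax(0, disc))
    t1 <- -b - s
    t2 <- -b + s
    # of the forward intersections take the one nearer the vertex plane
    z1 <- O[, 3] + t1 * D[, 3]
    z2 <- O[, 3] + t2 * D[, 3]
    bad1 <- t1 <= 1e-9
    bad2 <- t2 <= 1e-9
    d1 <- ifelse(bad1, Inf, abs(z1 - e$vertex_z))
    d2 <- ifelse(bad2, Inf, abs(z2 - e$vertex_z))
    t <- ifelse(d1 <= d2, t1, t2)
    miss <- miss | !is.finite(pmin(d1, d2))
    P <- O + t * D
    r2 <- P[, 1]^2 + P[, 2]^2
    vign <- !miss & r2 > e$aperture_radius^2
    N <- sweep(P, 2, C) / abs(R)
    flip <- rowSums(N * D) > 0
    N[flip, ] <- -N[flip, ]
    sn <- .snell(D, N, e$n_before / e$n_after)
    ok <- !miss & !vign & !sn$tir
    rows <- which(a)[ok]
    rs$O[rows, ] <- P[ok, , drop = FALSE]
    rs$D[rows, ] <- sn$D[ok, , drop = FALSE]
    idx <- rep(FALSE, length(rs$alive))
    idx[which(a)[miss]] <- TRUE; rs <- .kill(rs, idx, "miss")
    idx[] <- FALSE; idx[which(a)[vign]] <- TRUE; rs <- .kill(rs, idx, "vignetted")
    idx[] <- FALSE; idx[which(a)[sn$tir & !miss & !vign]] <- TRUE
    rs <- .kill(rs, idx, "tir")
    return(rs)
  }

  # planar elements: aperture, planar interface, thin lens
  dz <- e$vertex_z - O[, 3]
  fwd <- D[, 3] > 1e-12 | abs(dz) < 1e-12
  t <- dz / D[, 3]
  P <- O + t * D
  r2 <- P[, 1]^2 + P[, 2]^2
  vign <- fwd & r2 > e$aperture_radius^2
  ok <- fwd & !vign

  tir <- rep(FALSE, nrow(D))
  if (e$type == "thin_lens") {
    # ideal lens: exit ray heads to where the parallel central ray crosses
    # the back focal plane
    slx <- D[, 1] / D[, 3]
    sly <- D[, 2] / D[, 3]
    Fp <- cbind(slx * e$efl, sly * e$efl, e$vertex_z + e$efl)
    Dn <- Fp - cbind(P[, 1], P[, 2], e$vertex_z)
    Dn <- Dn / sqrt(rowSums(Dn^2))
    Dn <- Dn * sign(Dn[, 3])
  } else if (e$type == "sphere" && e$n_before != e$n_after) {
    sn <- .snell(D, matrix(rep(c(0, 0, -1), each = nrow(D)), ncol = 3),
                 e$n_before / e$n_after)
    tir <- sn$tir
    ok <- ok & !tir
    Dn <- sn$D
  } else {
    Dn <- D
  }

  rows <- which(a)[ok]
  rs$O[rows, ] <- P[ok, , drop = FALSE]
  rs$D[rows, ] <- Dn[ok, , drop = FALSE]
  idx <- rep(FALSE, length(rs$alive))
  idx[which(a)[!fwd]] <- TRUE; rs <- .kill(rs, idx, "miss")
  idx[] <- FALSE; idx[which(a)[vign]] <- TRUE; rs <- .kill(rs, idx, "vignetted")
  idx[] <- FALSE; idx[which(a)[tir & fwd & !vign]] <- TRUE; rs <- .kill(rs, idx, "tir")
  rs
}

# Trace a ray bundle to the sensor plane. Returns hits (n x 2, NA for dead),
# alive flags and reasons.
.trace_bundle <- function(train, O, D) {
  rs <- .rays(O, D)
  for (e in train$elements) rs <- .through_element(rs, e)
  n <- length(rs$alive)
  hits <- matrix(NA_real_, n, 2)
  if (any(rs$alive)) {
    a <- rs$alive
    t <- (train$sensor_z - rs$O[a, 3]) / rs$D[a, 3]
    P <- rs$O[a, , drop = FALSE] + t * rs$D[a, , drop = FALSE]
    hits[a, ] <- P[, 1:2]
  }
  list(hits = hits, alive = rs$alive, reason = rs$reason)
}

#' Refract a single ray at a spherical surface
#'
#' Vector Snell refraction, with vignetting (aperture miss) and total internal
#' reflection marking the ray dead rather than erroring.
#'
#' @param r A [ray()].
#' @param surface A [spherical_surface()] (curvature radius 0 = planar).
#' @return The refracted `ps_ray`; `alive = FALSE` with a `reason` of
#'   `"miss"`, `"vignetted"` or `"tir"` when the ray did not make it through.
#' @examples
#' s <- spherical_surface(0, 0, 10, 1, 1.5)
#' r <- refract_ray(ray(c(0, 0, -1), c(sin(pi / 6), 0, cos(pi / 6))), s)
#' asin(r$direction[1]) * 180 / pi # 19.47 degrees
#' @export
refract_ray <- function(r, surface) {
  stopifnot(inherits(r, "ps_ray"), inherits(surface, "ps_element"))
  if (!r$alive) return(r)
  rs <- .rays(r$origin, r$direction)
  rs <- .through_element(rs, surface)
  r$origin <- rs$O[1, ]
  r$direction <- rs$D[1, ]
  r$alive <- rs$alive[1]
  r$reason <- rs$reason[1]
  r
}

#' Trace one ray through a train
#'
#' @param train A `ps_train`.
#' @param r A [ray()] starting at the object plane.
#' @return A tibble with one row per surface intersection plus the sensor
#'   plane: `element`, `x`, `y`, `z`, `alive`. Dead rays carry a partial path.
#' @examples
#' tr <- build_iphone2g_microscope()
#' trace_ray(tr, ray(c(0, 0, tr$object_z), c(0, 0, 1)))
#' @export
trace_ray <- function(train, r) {
  stopifnot(inherits(train, "ps_train"), inherits(r, "ps_ray"))
  if (!length(train$elements)) stop("empty optical train")
  rs <- .rays(r$origin, r$direction)
  path <- list(tibble::tibble(element = "object", x = r$origin[1],
                              y = r$origin[2], z = r$origin[3], alive = TRUE))
  for (i in seq_along(train$elements)) {
    rs <- .through_element(rs, train$elements[[i]])
    if (!rs$alive[1]) break
    path[[length(path) + 1]] <- tibble::tibble(
      element = paste0(train$elements[[i]]$type, "_", i),
      x = rs$O[1, 1], y = rs$O[1, 2], z = rs$O[1, 3], alive = TRUE)
  }
  if (rs$alive[1]) {
    t <- (train$sensor_z - rs$O[1, 3]) / rs$D[1, 3]
    P <- rs$O[1, ] + t * rs$D[1, ]
    path[[length(path) + 1]] <- tibble::tibble(
      element = "sensor", x = P[1], y = P[2], z = P[3], alive = TRUE)
  } else {
    path[[length(path) + 1]] <- tibble::tibble(
      element = paste0("dead_", rs$reason[1]), x = NA_real_, y = NA_real_,
      z = NA_real_, alive = FALSE)
  }
  dplyr::bind_rows(path)
}

# Deterministic concentric-ring fan from a single object point: rings at
# area-uniform radii in direction space (uniform pupil fill), so spot moments
# converge quickly with ring count.
.ring_fan <- function(point, sin_theta_max, n_rings = 12, n_az = 8) {
  ss <- sin_theta_max * sqrt((seq_len(n_rings) - 0.5) / n_rings)
  phis <- 2 * pi * (seq_len(n_az) - 1) / n_az
  g <- expand.grid(s = ss, phi = phis)
  th <- asin(g$s)
  D <- cbind(sin(th) * cos(g$phi), sin(th) * sin(g$phi), cos(th))
  D <- rbind(c(0, 0, 1), D) # chief/axial ray first
  O <- matrix(rep(point, nrow(D)), ncol = 3, byrow = TRUE)
  list(O = O, D = D)
}
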