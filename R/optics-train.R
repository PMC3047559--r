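#' Optical elements and trains
#'
#' An optical train is an ordered sequence of elements along the +z optical
#' axis (object side at negative z), followed by a flat sensor. Supported
#' elements are refracting spherical surfaces (a curvature radius of 0 encodes
#' a planar interface), pure aperture stops, and ideal thin lenses. All
#' distances are millimetres; angles at the API surface are degrees.
#'
#' @param vertex_z Axial position of the element vertex (mm).
#' @param curvature_radius Signed curvature radius (mm); positive when the
#'   centre of curvature lies to the right (+z) of the vertex; 0 means planar.
#' @param aperture_radius Clear semi-aperture (mm); rays beyond it are killed.
#' @param n_before,n_after Refractive indices on the object/image side.
#' @return An element object of class `ps_element`.
#' @examples
#' spherical_surface(-0.5, 0.5, 0.5, 1, 1.5168)
#' @export
spherical_surface <- function(vertex_z, curvature_radius, aperture_radius,
                              n_before, n_after) {
  stopifnot(aperture_radius > 0, n_before >= 1, n_after >= 1)
  structure(list(type = "sphere", vertex_z = vertex_z,
                 curvature_radius = curvature_radius,
                 aperture_radius = aperture_radius,
                 n_before = n_before, n_after = n_after),
            class = "ps_element")
}

#' @rdname spherical_surface
#' @export
aperture_stop <- function(vertex_z, aperture_radius) {
  stopifnot(aperture_radius > 0)
  structure(list(type = "aperture", vertex_z = vertex_z,
                 curvature_radius = 0, aperture_radius = aperture_radius,
                 n_before = 1, n_after = 1),
            class = "ps_element")
}

#' @rdname spherical_surface
#' @param efl Effective focal length of an ideal thin lens (mm).
#' @export
thin_lens <- function(vertex_z, efl, aperture_radius) {
  stopifnot(efl != 0, aperture_radius > 0)
  structure(list(type = "thin_lens", vertex_z = vertex_z, efl = efl,
                 curvature_radius = 0, aperture_radius = aperture_radius,
                 n_before = 1, n_after = 1),
            class = "ps_element")
}

#' Sensor model
#'
#' @param width_mm,height_mm Active sensor dimensions (mm).
#' @param pixel_pitch_um Pixel pitch (micrometres).
#' @return A `ps_sensor` object.
#' @export
sensor_model <- function(width_mm, height_mm, pixel_pitch_um) {
  stopifnot(width_mm > 0, height_mm > 0, pixel_pitch_um > 0)
  structure(list(width_mm = width_mm, height_mm = height_mm,
                 pixel_pitch_um = pixel_pitch_um),
            class = "ps_sensor")
}

#' Assemble an optical train
#'
#' @param elements List of `ps_element` objects, object side first; vertex
#'   positions must be strictly increasing.
#' @param sensor A [sensor_model()].
#' @param sensor_z Axial position of the sensor plane (mm); must lie behind
#'   the last element.
#' @param object_z Default object (sample) plane position (mm, negative).
#' @return A `ps_train` object.
#' @export
optical_train <- function(elements, sensor, sensor_z, object_z) {
  if (!length(elements)) stop("optical train needs at least one element")
  zs <- vapply(elements, `[[`, numeric(1), "vertex_z")
  if (any(diff(zs) <= 0)) stop("element vertex_z must be strictly increasing")
  if (sensor_z <= zs[length(zs)]) stop("sensor must lie behind the last element")
  structure(list(elements = elements, sensor = sensor,
                 sensor_z = sensor_z, object_z = object_z),
            class = "ps_train")
}

#' @export
print.ps_train <- function(x, ...) {
  cat(sprintf("<optical train: %d elements, sensor %.2fx%.2f mm @ z=%.3f, object z=%.3f>\n",
              length(x$elements), x$sensor$width_mm, x$sensor$height_mm,
              x$sensor_z, x$object_z))
  for (e in x$elements)
    cat(sprintf("  %-9s z=%8.4f  R=%8.4f  ap=%.3f  n %.4f->%.4f%s\n",
                e$type, e$vertex_z, e$curvature_radius, e$aperture_radius,
                e$n_before, e$n_after,
                if (e$type == "thin_lens") sprintf("  efl=%.3f", e$efl) else ""))
  invisible(x)
}

#' A light ray
#'
#' @param origin Numeric length-3 position (mm).
#' @param direction Numeric length-3 direction; normalised internally.
#' @param wavelength_nm Wavelength (nm), > 0.
#' @return A `ps_ray` object with fields `origin`, `direction`,
#'   `wavelength_nm`, `alive` and `reason` (why a dead ray died).
#' @export
ray <- function(origin, direction, wavelength_nm = 550) {
  stopifnot(length(origin) == 3, length(direction) == 3, wavelength_nm > 0)
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("direction must be non-zero")
  structure(list(origin = as.numeric(origin),
                 direction = as.numeric(direction) / nrm,
                 wavelength_nm = wavelength_nm, alive = TRUE, reason = NA_character_),
            class = "ps_ray")
}

#' Ball-lens phone microscope prescription
#'
#' Builds the imaging train of a clip-on microscope: a glass ball objective in
#' front of a fixed-focus phone camera, with a field aperture between ball and
#' camera and the sensor at the phone lens's focal plane. Defaults reproduce a
#' 1 mm crown-glass ball with a 0.8 mm field aperture on a phone camera with a
#' 3.36 mm EFL lens and a 3.55 x 2.68 mm, 2.2 um-pitch sensor. The ball centre
#' sits at z = 0; the default object plane is the paraxial front focus,
#' nD/(4(n-1)) in front of the centre.
#'
#' @param ball_diameter_mm Ball lens diameter (mm).
#' @param n_ball Ball glass refractive index.
#' @param aperture_diameter_mm Field aperture diameter (mm).
#' @param phone_efl_mm Phone camera lens effective focal length (mm).
#' @param aperture_gap_mm Gap between ball rear vertex and the field aperture.
#' @param lens_gap_mm Gap between ball rear vertex and the phone lens.
#' @param sensor A [sensor_model()]; default is the 3.55 x 2.68 mm, 2.2 um
#'   phone sensor.
#' @return A `ps_train`.
#' @examples
#' tr <- build_iphone2g_microscope()
#' tr
#' @export
build_iphone2g_microscope <- function(ball_diameter_mm = 1,
                                      n_ball = 1.5168,
                                      aperture_diameter_mm = 0.8,
                                      phone_efl_mm = 3.36,
                                      aperture_gap_mm = 0.05,
                                      lens_gap_mm = 1.0,
                                      sensor = sensor_model(3.55, 2.68, 2.2)) {
  stopifnot(ball_diameter_mm > 0, n_ball > 1, aperture_diameter_mm > 0)
  R <- ball_diameter_mm / 2
  z_ap <- R + aperture_gap_mm
  z_pl <- R + lens_gap_mm
  efl_ball <- ball_efl(ball_diameter_mm, n_ball)
  optical_train(
    elements = list(
      spherical_surface(-R, R, R, 1, n_ball),
      spherical_surface(R, -R, R, n_ball, 1),
      aperture_stop(z_ap, aperture_diameter_mm / 2),
      thin_lens(z_pl, phone_efl_mm, 1.5)
    ),
    sensor = sensor,
    sensor_z = z_pl + phone_efl_mm,
    object_z = -efl_ball
  )
}

#' Paraxial focal length of a ball lens
#'
#' EFL referenced to the ball centre: nD / (4 (n - 1)).
#'
#' @param diameter_mm Ball diameter (mm).
#' @param n Refractive index.
#' @return EFL in mm.
#' @examples
#' ball_efl(1, 1.5168) # 0.7337 mm
#' ball_efl(1, 2)      # 0.5 mm: focus on the rear surface
#' @export
ball_efl <- function(diameter_mm, n) {
  stopifnot(diameter_mm > 0, n > 1)
  n * diameter_mm / (4 * (n - 1))
}

#' Read / write a lens prescription file
#'
#' YAML files with a `surfaces` list (`type`, `vertex_z`, `radius`, `aperture`,
#' `n_before`, `n_after`, `efl`), a `sensor` block (`width_mm`, `height_mm`,
#' `pixel_pitch_um`, `z`) and an `object_z` entry.
#'
#' @param path File path.
#' @return `read_prescription()` returns a `ps_train`.
#' @export
read_prescription <- function(path) {
  cfg <- yaml::read_yaml(path)
  elems <- lapply(cfg$surfaces, function(s) {
    type <- s$type %||% "sphere"
    switch(type,
      sphere = spherical_surface(s$vertex_z, s$radius %||% 0, s$aperture,
                                 s$n_before %||% 1, s$n_after %||% 1),
      aperture = aperture_stop(s$vertex_z, s$aperture),
      thin_lens = thin_lens(s$vertex_z, s$efl, s$aperture),
      stop("unknown surface type: ", type))
  })
  sn <- cfg$sensor
  optical_train(elems,
                sensor_model(sn$width_mm, sn$height_mm, sn$pixel_pitch_um),
                sensor_z = sn$z, object_z = cfg$object_z)
}

#' @rdname read_prescription
#' @param train A `ps_train`.
#' @export
write_prescription <- function(train, path) {
  surf <- lapply(train$elements, function(e) {
    out <- list(type = e$type, vertex_z = e$vertex_z, aperture = e$aperture_radius)
    if (e$type == "sphere") {
      out$radius <- e$curvature_radius
      out$n_before <- e$n_before
      out$n_after <- e$n_after
    }
    if (e$type == "thin_lens") out$efl <- e$efl
    out
  })
  yaml::write_yaml(list(
    surfaces = surf,
    sensor = list(width_mm = train$sensor$width_mm,
                  height_mm = train$sensor$height_mm,
                  pixel_pitch_um = train$sensor$pixel_pitch_um,
                  z = train$sensor_z),
    object_z = train$object_z
  ), path, precision = 12)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
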