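# shared fixtures, all built in code

# ideal thin-lens imaging train: object at -u, lens at 0, sensor at v
thin_lens_train <- function(f = 10, u = 15, v = 30, ap = 4) {
  optical_train(list(thin_lens(0, f, ap)),
                sensor = sensor_model(10, 10, 2),
                sensor_z = v, object_z = -u)
}

# lone glass ball of diameter D centred at z = 0 (no aperture/phone lens)
lone_ball_train <- function(D = 1, n = 1.5168) {
  R <- D / 2
  optical_train(list(spherical_surface(-R, R, R, 1, n),
                     spherical_surface(R, -R, R, n, 1)),
                sensor = sensor_model(10, 10, 2),
                sensor_z = 5, object_z = -ball_efl(D, n))
}

# z at which a traced ray crosses the optical axis (x = 0), from its exit state
axis_crossing_z <- function(train, r) {
  path <- trace_ray(train, r)
  stopifnot(all(path$alive))
  # re-trace to recover exit direction: use last two path points before sensor
  p1 <- path[nrow(path) - 1, ]
  p2 <- path[nrow(path), ]
  dzdx <- (p2$z - p1$z) / (p2$x - p1$x)
  p1$z - p1$x * dzdx
}

smooth_texture <- function(shape = c(128, 128), seed = 7) {
  make_texture_scene(shape, kind = "speckle", correlation_px = 2, seed = seed)
}
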