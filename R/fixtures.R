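#' Miniature verification fixtures
#'
#' Small scenes that solve in seconds, used by the test suite and handy for
#' quick interactive checks:
#' \describe{
#'   \item{`bowl_lossless`}{0.45 MHz bowl (24 mm aperture, 20 mm focal
#'     length, no hole) in lossless linear water on a 15 x 40 mm
#'     axisymmetric lambda/12 grid; focal gain comparable against
#'     [oneil_axial()].}
#'   \item{`plate_in_water`}{the same bowl with a small acrylic shell
#'     (T = 4 mm, R = 30 mm, D = 5 mm).}
#'   \item{`slab_1d`}{a 1-D water track with an 8 mm acrylic slab, for
#'     transmission checks against [layer_transmission()]; returned as an
#'     argument list for [simulate_1d()].}
#' }
#'
#' @param name Fixture name.
#' @return A `fus_scene` for the 2-D fixtures; a named list of
#'   [simulate_1d()] arguments (class `fus_fixture_1d`) for `slab_1d`.
#' @export
make_fixture <- function(name) {
  known <- c("bowl_lossless", "plate_in_water", "slab_1d")
  if (!name %in% known)
    abort(sprintf("unknown fixture '%s'; available: %s",
                  name, paste(known, collapse = ", ")),
          class = "fus_unknown_fixture")
  if (name == "slab_1d") {
    return(structure(list(
      length_mm = 60, dx_mm = 1482 / 0.9e6 / 24 * 1e3,
      frequency_hz = 0.9e6, p0 = 1,
      background = water_material(),
      segments = list(list(from_mm = 25, to_mm = 33,
                           material = acrylic_material())),
      probe_mm = numeric(), nonlinear = FALSE),
      class = "fus_fixture_1d"))
  }
  tx <- transducer(frequency_hz = 0.45e6, aperture_mm = 24,
                   focal_length_mm = 20, hole_mm = 0,
                   surface_pressure_pa = 1e4)
  lossless_water <- material(998.2, 1482, absorption = 0,
                             nonlinearity = 3.5, label = "water (lossless)")
  plate <- if (name == "plate_in_water")
    plate_spec(4, 30, 5, acrylic_material())
  # lambda/12 grid: fine enough for close oracle agreement, still < 1 s
  dx <- 1482 / 0.45e6 / 12 * 1e3
  c_max <- if (is.null(plate)) 1482 else plate$material$sound_speed
  dt <- min(0.85 * dx * 1e-3 / (c_max * sqrt(2)), 1 / 0.45e6 / 20) * 1e9
  g <- build_grid("axisymmetric", dx, dt, c(r = 15, z = 40),
                  c_max = c_max, frequency_hz = 0.45e6)
  scene(tx, plate = plate, water = lossless_water, grid = g)
}
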