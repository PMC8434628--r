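test_that("grid construction enforces the Courant bound", {
  # full-scale 3-D reference grid: 0.2 mm, 10 ns, stable up to 5000 m/s
  g <- build_grid("3d", 0.2, 10, c(x = 100, y = 100, z = 100),
                  c_max = 5000, frequency_hz = 0.9e6)
  expect_true(all(g$dims >= 500))
  expect_equal(g$dt_max_ns, 0.2e-3 / (5000 * sqrt(3)) * 1e9, tolerance = 1e-9)
  expect_true(g$dx_le_lambda8)
  expect_error(
    build_grid("3d", 0.2, 30, c(x = 100, y = 100, z = 100), c_max = 5000),
    class = "fus_invalid_config")

  g2 <- build_grid("axisymmetric", 0.4, 20, c(r = 50, z = 100))
  expect_equal(range(g2$r_mm), c(0, 50))
  expect_equal(range(g2$z_mm), c(0, 100))
})

test_that("plate rasterization has the right on-axis chord and volume", {
  tx <- transducer()
  g <- build_grid("axisymmetric", 0.2, 10, c(r = 65, z = 100),
                  c_max = 2600, frequency_hz = 0.9e6)
  pl <- plate_spec(8, 60, 10)
  mask <- rasterize_plate(pl, g, tx)

  # on-axis chord equals the thickness to within one cell
  chord <- sum(mask[1, ]) * g$dx_mm
  expect_lt(abs(chord - 8), 1.01 * g$dx_mm + 0.2)

  # masked volume (ring-weighted) vs analytic transducer-facing half shell
  ring <- 2 * pi * g$r_mm * g$dx_mm^2
  ring[1] <- pi * (g$dx_mm / 2)^2 * g$dx_mm
  vol <- sum(ring * rowSums(mask))
  vol_exact <- 2 * pi / 3 * (60^3 - 52^3)
  expect_lt(abs(vol / vol_exact - 1), 0.02)
})

test_that("rasterization converges to the flat slab limit for large R", {
  tx <- transducer()
  g <- build_grid("axisymmetric", 0.2, 10, c(r = 40, z = 100),
                  c_max = 2600, frequency_hz = 0.9e6)
  mask <- rasterize_plate(plate_spec(8, 5000, 10), g, tx)
  ring <- 2 * pi * g$r_mm * g$dx_mm^2
  ring[1] <- pi * (g$dx_mm / 2)^2 * g$dx_mm
  vol <- sum(ring * rowSums(mask))
  slab <- pi * max(g$r_mm)^2 * 8
  expect_lt(abs(vol / slab - 1), 0.02)
})

test_that("rasterization volume is resolution-consistent", {
  tx <- transducer()
  vol_at <- function(dx) {
    g <- build_grid("axisymmetric", dx, 10, c(r = 65, z = 100), c_max = 2600)
    mask <- rasterize_plate(plate_spec(8, 60, 10), g, tx)
    ring <- 2 * pi * g$r_mm * dx^2
    ring[1] <- pi * (dx / 2)^2 * dx
    sum(ring * rowSums(mask))
  }
  expect_lt(abs(vol_at(0.2) / vol_at(0.4) - 1), 0.01)
})

test_that("impossible plate placements are rejected", {
  # plate running past the far domain face
  expect_error(
    scene(transducer(), plate = plate_spec(8, 60, 80), resolution = "coarse"),
    class = "fus_geometry_error")
  # domain too small for the bowl itself
  expect_error(
    scene(transducer(), domain_mm = c(r = 30, z = 100)),
    class = "fus_geometry_error")
})

test_that("medium maps partition the domain with exactly one material", {
  sc <- scene(transducer(), plate = plate_spec(8, 60, 10),
              resolution = "coarse")
  maps <- build_medium_maps(sc)
  w <- water_material(); a <- acrylic_material()
  expect_true(all(maps$c %in% c(w$sound_speed, a$sound_speed)))
  expect_equal(maps$c == a$sound_speed, maps$plate_mask,
               ignore_attr = TRUE)
  expect_equal(maps$rho[!maps$plate_mask],
               rep(w$density, sum(!maps$plate_mask)))
  # delta derived from absorption at the drive frequency
  expect_equal(max(maps$delta), diffusivity(a, 0.9e6), tolerance = 1e-12)
  # zero-absorption media give identically zero delta
  sc0 <- scene(transducer(), water = lossless_water(), resolution = "coarse")
  expect_true(all(build_medium_maps(sc0)$delta == 0))
})

test_that("source rasterizes the annular cap with the documented extent", {
  sc <- scene(transducer(), resolution = "coarse")
  src <- build_source(sc$transducer, sc$grid)
  expect_gte(min(src$r_mm), 25 - sc$grid$dx_mm)
  expect_lte(max(src$r_mm), 50 + sc$grid$dx_mm)
  # every node's cap depth matches the bowl surface at that node's radius
  expect_equal(src$cap_z_mm, 80 - sqrt(80^2 - src$r_mm^2), tolerance = 1e-9)
  # rasterized z is within half a cell of the true surface
  expect_lt(max(abs(src$z_mm - src$cap_z_mm)), sc$grid$dx_mm / 2 + 1e-9)
  # drive amplitude attribute follows the transducer setting exactly
  tx2 <- transducer(surface_pressure_pa = 2e4)
  src2 <- build_source(tx2, sc$grid)
  expect_equal(attr(src2, "amplitude_pa"), 2 * attr(src, "amplitude_pa"))
})

test_that("axisymmetric and 3-D rasterizations agree on the axial profile", {
  pl <- plate_spec(4, 30, 5)
  sca <- mini_scene(6, plate = pl, water = water_material())
  sc3 <- mini_scene(6, mode = "3d", plate = pl, water = water_material())
  ma <- build_medium_maps(sca)
  m3 <- build_medium_maps(sc3)
  ix <- which.min(abs(sc3$grid$x_mm)); iy <- which.min(abs(sc3$grid$y_mm))
  expect_equal(ma$c[1, ], m3$c[ix, iy, ], ignore_attr = TRUE)
})

test_that("scene YAML round-trips and schema errors name the missing key", {
  sc <- scene(transducer(), plate = plate_spec(8, 60, 10),
              resolution = "coarse")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scene_yaml(sc, path)
  sc2 <- read_scene_yaml(path)
  expect_equal(sc2$plate$thickness_mm, 8)
  expect_equal(sc2$transducer$frequency_hz, 0.9e6)
  expect_equal(sc2$water$density, 998.2)

  cfg <- yaml::read_yaml(path)
  cfg$transducer$focal_length_mm <- NULL
  yaml::write_yaml(cfg, path)
  expect_error(read_scene_yaml(path), "focal_length_mm",
               class = "fus_schema_error")
})
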