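# one expectation per named check: a failed vector prints which checks broke
expect_all <- function(checks) {
  testthat::expect_equal(checks,
                         stats::setNames(rep(TRUE, length(checks)),
                                         names(checks)))
}

# shared fixtures: expensive solves are cached for the whole test run
fus_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = fus_test_cache))
    assign(key, force(expr), envir = fus_test_cache)
  get(key, envir = fus_test_cache)
}

lossless_water <- function() material(998.2, 1482, 0, 3.5, "lossless water")

mini_tx <- function(p0 = 1e4)
  transducer(frequency_hz = 0.45e6, aperture_mm = 24, focal_length_mm = 20,
             hole_mm = 0, surface_pressure_pa = p0)

# miniature bowl scene at lambda/div resolution (runs in well under a second
# axisymmetric; a few seconds in 3-D at lambda/6)
mini_scene <- function(div = 12, mode = "axisymmetric", p0 = 1e4,
                       water = lossless_water(), plate = NULL) {
  lam_mm <- 1482 / 0.45e6 * 1e3
  dx <- lam_mm / div
  d <- if (mode == "3d") 3 else 2
  c_max <- max(water$sound_speed,
               if (!is.null(plate)) plate$material$sound_speed else 0)
  dt <- min(0.85 * dx * 1e-3 / (c_max * sqrt(d)), 1 / 0.45e6 / 20) * 1e9
  ext <- if (mode == "3d") c(x = 30, y = 30, z = 40) else c(r = 15, z = 40)
  g <- build_grid(mode, dx, dt, ext, c_max = c_max, frequency_hz = 0.45e6)
  scene(mini_tx(p0), plate = plate, water = water, grid = g, mode = mode)
}

mini_field <- function(div = 12)
  cached(paste0("mini_lin_", div),
         run_to_steady(mini_scene(div), solver_settings(linear = TRUE)))

# ---- the full-scale calibrated study pipeline (coarse preset) ------------
acc_settings <- function() solver_settings()

acc_p0 <- function() cached("acc_p0", {
  calibrate_source(scene(transducer(), resolution = "coarse"),
                   549.3e3, acc_settings())
})

acc_tx <- function() transducer(surface_pressure_pa = acc_p0())

acc_water <- function() cached("acc_water", {
  focal_metrics(run_to_steady(scene(acc_tx(), resolution = "coarse"),
                              acc_settings()))
})

acc_plate <- function() cached("acc_plate", {
  sc <- scene(acc_tx(), plate = plate_spec(8, 60, 10), resolution = "coarse")
  focal_metrics(run_to_steady(sc, acc_settings()), z_min_mm = 40)
})

acc_sweep <- function(par) cached(paste0("acc_sweep_", par), {
  suppressWarnings(
    run_sweep(sweep_spec(par, transducer = acc_tx()), acc_settings()))
})
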