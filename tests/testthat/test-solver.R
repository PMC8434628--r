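test_that("stability report reproduces the closed-form Courant bounds", {
  g <- build_grid("3d", 0.2, 10, c(x = 100, y = 100, z = 100), c_max = 5000)
  rep1 <- check_stability(g, 5000)
  expect_equal(rep1$dt_max_ns, 23.094, tolerance = 1e-4)
  expect_true(rep1$pass)
  rep2 <- check_stability(g, 1482)
  expect_equal(rep2$dt_max_ns, 77.915, tolerance = 1e-4)
  # dt_max is inversely proportional to the fastest speed
  expect_equal(check_stability(g, 2 * 1482)$dt_max_ns, rep2$dt_max_ns / 2)
})

test_that("a zero field with no drive stays identically zero", {
  s <- simulate_1d(20, 0.5, 0.9e6, p0 = 0, background = lossless_water(),
                   n_cycles = 5)
  expect_true(all(s$amplitude == 0))
  expect_true(all(s$probes == 0))
})

test_that("numerical phase speed is within 0.5 % of c at 8 ppw, CFL 0.95", {
  f <- 0.9e6; lam_mm <- 1482 / f * 1e3
  d1 <- 20; d2 <- 50   # probes 30 mm apart, ~16.4 wavelengths
  s <- simulate_1d(70, lam_mm / 8, f, p0 = 1, background = lossless_water(),
                   cfl = 0.95, n_cycles = 30, probe_mm = c(d1, d2))
  spc <- s$steps_per_cycle
  n <- nrow(s$probes)
  win <- (n - 10 * spc + 1):n                # last 10 whole cycles
  ph <- function(x) {
    sp <- stats::fft(x[win])
    Arg(sp[10 + 1])                          # drive bin after 10 cycles
  }
  dphi <- ph(s$probes[, 1]) - ph(s$probes[, 2])
  k0 <- 2 * pi * f / 1482
  m <- round((k0 * (d2 - d1) * 1e-3 - dphi) / (2 * pi))
  k_num <- (dphi + 2 * pi * m) / ((d2 - d1) * 1e-3)
  c_num <- 2 * pi * f / k_num
  expect_lt(abs(c_num / 1482 - 1), 0.005)
})

test_that("plane-wave decay matches exp(-alpha x) within 2 % over 20 lambda", {
  f <- 0.9e6; lam_mm <- 1482 / f * 1e3
  med <- material(998.2, 1482, absorption = 18)   # 16.2 Np/m at 0.9 MHz
  s <- simulate_1d(70, lam_mm / 12, f, p0 = 1, background = med,
                   cfl = 0.6, n_cycles = 40)
  x1 <- 18
  x2 <- x1 + 20 * lam_mm                          # ~33 mm apart
  a1 <- s$amplitude[which.min(abs(s$x_mm - x1))]
  a2 <- s$amplitude[which.min(abs(s$x_mm - x2))]
  alpha_meas <- -log(a2 / a1) / ((x2 - x1) * 1e-3)
  expect_lt(abs(alpha_meas / 16.2 - 1), 0.02)
  # the amplitude ratio itself agrees with the closed-form oracle
  expect_equal(a2 / a1, plane_wave_decay(16.2, (x2 - x1) * 1e-3),
               tolerance = 0.05)
})

test_that("Mur boundary reflects < 1 % at normal incidence", {
  f <- 0.9e6; lam_mm <- 1482 / f * 1e3
  s <- simulate_1d(60, lam_mm / 12, f, p0 = 1, background = lossless_water(),
                   cfl = 0.95, n_cycles = 40, source = "soft")
  sel <- s$x_mm > 20 & s$x_mm < 50           # SWR between source and far end
  swr <- max(s$amplitude[sel]) / min(s$amplitude[sel])
  expect_lt((swr - 1) / (swr + 1), 0.01)
})

test_that("1-D transmission into a half-space step follows 2Z2/(Z1+Z2)", {
  f <- 0.9e6; lam_mm <- 1482 / f * 1e3
  w <- material(998.2, 1482, 0); a <- material(1203, 2600, 0)
  s <- simulate_1d(60, lam_mm / 24, f, p0 = 1, background = w, cfl = 0.6,
                   n_cycles = 60, source = "soft",
                   segments = list(list(from_mm = 30, to_mm = 60,
                                        material = a)))
  amp <- s$amplitude; x <- s$x_mm
  inc <- (max(amp[x > 10 & x < 28]) + min(amp[x > 10 & x < 28])) / 2
  tr <- (max(amp[x > 35 & x < 55]) + min(amp[x > 35 & x < 55])) / 2
  expect_lt(abs(tr / inc / interface_transmission(w, a) - 1), 0.02)
})

test_that("steady slab transmission matches the lossy layer closed form", {
  fx <- make_fixture("slab_1d")
  s <- simulate_1d(fx$length_mm, fx$dx_mm, fx$frequency_hz, p0 = fx$p0,
                   background = fx$background, segments = fx$segments,
                   cfl = 0.6, n_cycles = 60, source = "soft")
  amp <- s$amplitude; x <- s$x_mm
  inc <- (max(amp[x > 8 & x < 23]) + min(amp[x > 8 & x < 23])) / 2
  tr <- (max(amp[x > 36 & x < 55]) + min(amp[x > 36 & x < 55])) / 2
  T_exact <- layer_transmission(water_material(), acrylic_material(), 8, 0.9e6)
  expect_lt(abs(tr / inc / T_exact - 1), 0.03)
})

test_that("second harmonic of a nonlinear plane wave follows the Fubini solution", {
  f <- 0.9e6; lam_mm <- 1482 / f * 1e3
  w <- lossless_water()                      # beta = 3.5, no absorption
  k <- 2 * pi * f / w$sound_speed
  x_probe <- 20 * lam_mm                     # ~33 mm
  sigma <- 0.3
  eps <- sigma / (w$nonlinearity * k * x_probe * 1e-3)
  p0 <- eps * w$density * w$sound_speed^2    # ~1.5 MPa
  # lambda/32 so the second harmonic itself is well resolved; CFL near 1
  # keeps fundamental/harmonic phase speeds matched over the path
  s <- simulate_1d(45, lam_mm / 32, f, p0 = p0, background = w, cfl = 0.9,
                   n_cycles = 30, probe_mm = 2 + x_probe, nonlinear = TRUE)
  n <- nrow(s$probes)
  win <- (n - 20 * s$steps_per_cycle + 1):n  # ~20 cycles
  tt <- win * s$dt_s                          # drive is sin(omega (s+1) dt)
  proj <- function(h) {                       # direct harmonic projection
    Mod(2 * mean(s$probes[win, 1] * exp(-1i * h * 2 * pi * f * tt)))
  }
  b2 <- proj(2) / p0
  expect_lt(abs(b2 / fubini_harmonics(sigma, 2) - 1), 0.10)
})

test_that("linear-mode amplitude is exactly proportional to the drive", {
  f1 <- mini_field(12)
  sc2 <- mini_scene(12, p0 = 2e4)
  f2 <- run_to_steady(sc2, solver_settings(linear = TRUE))
  expect_equal(f2$amplitude, 2 * f1$amplitude, tolerance = 1e-12)
})

test_that("increasing thermoviscous loss never increases the focal peak", {
  peaks <- vapply(c(0, 0.5, 5), function(a) {
    sc <- mini_scene(12, water = material(998.2, 1482, a, 3.5))
    max(run_to_steady(sc, solver_settings(linear = TRUE))$amplitude)
  }, 0)
  expect_true(all(diff(peaks) < 0))
})

test_that("focal peak is grid-converged to < 3 % between successive refinements", {
  p12 <- find_focus(mini_field(12), z_min_mm = 8)$peak_pa
  f16 <- run_to_steady(mini_scene(16), solver_settings(linear = TRUE))
  p16 <- find_focus(f16, z_min_mm = 8)$peak_pa
  expect_lt(abs(p16 / p12 - 1), 0.03)
})

test_that("axisymmetric and 3-D solves agree on focal position and scale", {
  fa <- run_to_steady(mini_scene(6), solver_settings(linear = TRUE))
  f3 <- run_to_steady(mini_scene(6, mode = "3d"), solver_settings(linear = TRUE))
  ma <- find_focus(fa, z_min_mm = 8)
  m3 <- find_focus(f3, z_min_mm = 8)
  expect_lt(abs(ma$z_mm - m3$z_mm), fa$grid$dx_mm + 1e-9)  # within one cell
  expect_lt(abs(m3$peak_pa / ma$peak_pa - 1), 0.10)
})

test_that("divergent configurations raise a divergence error", {
  # a loss term far beyond its explicit-update stability limit must blow up:
  # the custom grid keeps the Courant-legal dt, so only the delta term is at
  # fault, and the solver aborts instead of returning garbage
  sc <- mini_scene(12, water = material(998.2, 1482, 682, 0))
  expect_error(
    suppressWarnings(run_to_steady(sc, solver_settings(linear = TRUE))),
    "divergence")
})
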