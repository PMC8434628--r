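#' Solver settings
#'
#' Controls the continuous-wave steady-state protocol.  The solve runs for
#' twice the slowest domain-traversal time plus `n_cycles` drive cycles; the
#' per-cell amplitude is the maximum |p| over the final `window_cycles`
#' cycles, recorded as two consecutive one-cycle windows whose relative
#' difference in global peak is the steady-state residual.
#'
#' @param n_cycles Drive cycles simulated beyond the double-traversal time.
#' @param window_cycles Final cycles used for amplitude extraction (>= 2).
#' @param linear If `TRUE`, drop the quadratic (beta) term: the field is then
#'   exactly proportional to the drive amplitude.  The thermoviscous loss
#'   term follows the medium maps regardless.
#' @param steady_tol Relative change of the global peak between the two
#'   recording cycles above which a non-convergence warning is raised.
#' @param blowup_pa Divergence guard: the solve aborts if |p| exceeds this.
#' @return An object of class `fus_settings`.
#' @export
solver_settings <- function(n_cycles = 15, window_cycles = 2, linear = FALSE,
                            steady_tol = 0.05, blowup_pa = 1e10) {
  if (n_cycles < 1 || window_cycles < 2) abort("need n_cycles >= 1, window_cycles >= 2")
  structure(list(n_cycles = n_cycles, window_cycles = window_cycles,
                 linear = linear, steady_tol = steady_tol,
                 blowup_pa = blowup_pa),
            class = "fus_settings")
}

#' Courant stability report
#'
#' Reports the explicit-scheme stability bound `dt_max = dx / (c_max sqrt(d))`
#' (d = 3 in 3-D, 2 for the axisymmetric stencil) for the fastest medium on
#' the grid, and whether the configured time step passes.
#'
#' @param grid A [build_grid()] result.
#' @param media A [build_medium_maps()] result, a `fus_material`, or a
#'   numeric maximum sound speed (m/s).  Defaults to the speed the grid was
#'   declared stable for.
#' @return A one-row tibble with `dt_ns`, `dt_max_ns`, `cfl` and `pass`.
#' @export
check_stability <- function(grid, media = NULL) {
  c_max <- if (is.null(media)) grid$c_max
  else if (inherits(media, "fus_medium_maps")) max(media$c)
  else if (inherits(media, "fus_material")) media$sound_speed
  else as.numeric(media)
  d <- if (grid$mode == "3d") 3 else 2
  dt_max_ns <- grid$dx_mm * 1e-3 / (c_max * sqrt(d)) * 1e9
  tibble(dt_ns = grid$dt_ns, dt_max_ns = dt_max_ns,
         cfl = grid$dt_ns / dt_max_ns, c_max = c_max,
         pass = grid$dt_ns <= dt_max_ns)
}

#' Run a scene to CW steady state
#'
#' Advances the Westervelt FDTD scheme under continuous sine drive until the
#' field is periodic, then extracts the per-cell steady-state pressure
#' amplitude.  Deterministic for a fixed scene and settings.
#'
#' @param scene A [scene()].
#' @param settings A [solver_settings()].
#' @return An object of class `fus_field`: amplitude array (Pa) on the grid,
#'   plus the scene, settings, steady-state residual and a provenance hash.
#' @examples
#' \donttest{
#' sc <- scene(resolution = "coarse")
#' fld <- run_to_steady(sc)
#' focal_metrics(fld)
#' }
#' @export
run_to_steady <- function(scene, settings = solver_settings()) {
  g <- scene$grid
  maps <- build_medium_maps(scene)
  stab <- check_stability(g, maps)
  if (!stab$pass)
    abort("invalid-config: time step unstable for the scene media",
          class = "fus_invalid_config")
  src <- build_source(scene$transducer, g)
  dt <- g$dt_ns * 1e-9
  period <- 1 / scene$transducer$frequency_hz
  spc <- max(2L, as.integer(round(period / dt)))
  diag_mm <- sqrt(sum(vapply(g$extent_mm, max, 0)^2))
  t_arr <- diag_mm * 1e-3 / min(maps$c)
  nsteps <- as.integer(ceiling((2 * t_arr + settings$n_cycles * period) / dt))
  half <- as.integer(round(settings$window_cycles / 2 * spc))
  recB0 <- nsteps - half; recA0 <- nsteps - 2L * half
  if (recA0 < 1L) abort("run too short for the amplitude window")

  omega <- scene$transducer$omega
  csim <- dispersion_tuned_c(maps$c, g$dx_mm * 1e-3, dt, omega)
  # phase-corrected staircase: each cap node is driven as a sample of the
  # true cap wavefront (axial offset projected on the local normal)
  k_src <- omega / dispersion_tuned_c(scene$water$sound_speed,
                                      g$dx_mm * 1e-3, dt, omega)
  phase <- -k_src * (src$z_mm - src$cap_z_mm) * 1e-3 * src$cos_normal
  if (g$mode == "axisymmetric") {
    res <- fdtd_run_axi(csim, maps$c, maps$rho, maps$delta, maps$beta,
                        g$dx_mm * 1e-3, dt,
                        src$i - 1L, src$j - 1L, phase,
                        scene$transducer$surface_pressure_pa,
                        scene$transducer$omega,
                        nsteps, recA0, recB0, recB0, nsteps,
                        !settings$linear, settings$blowup_pa)
    ampA <- res$ampA; ampB <- res$ampB
  } else {
    res <- fdtd_run_3d(c(csim), c(maps$c), c(maps$rho), c(maps$delta), c(maps$beta),
                       as.integer(g$dims), g$dx_mm * 1e-3, dt,
                       src$lin - 1L, phase,
                       scene$transducer$surface_pressure_pa,
                       scene$transducer$omega,
                       nsteps, recA0, recB0, recB0, nsteps,
                       !settings$linear, settings$blowup_pa)
    ampA <- array(res$ampA, dim = g$dims)
    ampB <- array(res$ampB, dim = g$dims)
  }
  pkA <- max(ampA); pkB <- max(ampB)
  residual <- abs(pkA - pkB) / max(pkB, .Machine$double.eps)
  if (residual > settings$steady_tol)
    warning(sprintf("steady-state residual %.3g exceeds tolerance %.3g",
                    residual, settings$steady_tol), call. = FALSE)
  structure(
    list(amplitude = pmax(ampA, ampB), grid = g, scene = scene,
         settings = settings, residual = residual, n_steps = nsteps,
         provenance = scene_hash(scene, settings)),
    class = "fus_field")
}

scene_hash <- function(scene, settings = NULL) {
  digest::digest(list(unclass_deep(scene), unclass_deep(settings)))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' @export
print.fus_field <- function(x, ...) {
  cat(sprintf(
    "<fus_field> %s grid %s, peak %.4g kPa, steady residual %.2g, %d steps\n",
    x$grid$mode, paste(x$grid$dims, collapse = " x "),
    max(x$amplitude) / 1e3, x$residual, x$n_steps))
  invisible(x)
}

#' @export
as_tibble.fus_field <- function(x, ...) {
  g <- x$grid
  if (g$mode == "axisymmetric")
    tibble(r_mm = rep(g$r_mm, times = length(g$z_mm)),
           z_mm = rep(g$z_mm, each = length(g$r_mm)),
           amplitude_pa = c(x$amplitude))
  else
    tibble(x_mm = rep(g$x_mm, times = prod(g$dims[2:3])),
           y_mm = rep(rep(g$y_mm, each = g$dims[1]), times = g$dims[3]),
           z_mm = rep(g$z_mm, each = prod(g$dims[1:2])),
           amplitude_pa = c(x$amplitude))
}

#' On-axis amplitude profile
#'
#' @param field A `fus_field`.
#' @return A tibble with `z_mm` and `amplitude_pa` along the beam axis.
#' @export
axial_profile <- function(field) {
  g <- field$grid
  amp <- if (g$mode == "axisymmetric") field$amplitude[1, ]
  else {
    ix <- which.min(abs(g$x_mm)); iy <- which.min(abs(g$y_mm))
    field$amplitude[ix, iy, ]
  }
  tibble(z_mm = g$z_mm, amplitude_pa = amp)
}

#' One-dimensional Westervelt test bench
#'
#' Runs the same FDTD scheme on a 1-D track: a continuous sine source near
#' the left end, Mur terminations at both ends, and optional material
#' segments along the track.  Used for verification against plane-wave
#' closed forms (dispersion, absorption, interface transmission, boundary
#' reflection, harmonic growth).
#'
#' @param length_mm Track length.
#' @param dx_mm Spatial step.
#' @param frequency_hz Drive frequency.
#' @param p0 Drive amplitude (Pa).
#' @param background Background [material()].
#' @param segments Optional list of `list(from_mm=, to_mm=, material=)`
#'   entries painted over the background.
#' @param cfl Courant number (`dt = cfl * dx / c_max`).
#' @param n_cycles Cycles beyond the double traversal time.
#' @param source_mm Source position.
#' @param probe_mm Positions whose full pressure time series is recorded.
#' @param nonlinear Keep the quadratic term?
#' @param source `"hard"` clamps the pressure at the source node (standard
#'   drive, reflects returning waves); `"soft"` adds the drive instead, so
#'   waves reflected back from interfaces pass through and are absorbed at
#'   the boundary — preferred for transmission measurements, where a hard
#'   source would close a reverberating cavity.
#' @return List with `x_mm`, `amplitude` (steady max |p| per node), `probes`
#'   (steps x probes matrix), `dt_s`, `steps_per_cycle`, `alpha_np_m` of the
#'   background at the drive frequency.
#' @export
simulate_1d <- function(length_mm, dx_mm, frequency_hz, p0 = 1,
                        background = water_material(), segments = NULL,
                        cfl = 0.95, n_cycles = 20, source_mm = 2,
                        probe_mm = numeric(), nonlinear = FALSE,
                        source = c("hard", "soft")) {
  source <- match.arg(source)
  x <- seq(0, length_mm, by = dx_mm)
  n <- length(x)
  mat_at <- rep(list(background), n)
  for (sg in segments %||% list()) {
    idx <- which(x >= sg$from_mm & x <= sg$to_mm)
    mat_at[idx] <- list(sg$material)
  }
  cvec <- vapply(mat_at, `[[`, 0, "sound_speed")
  rvec <- vapply(mat_at, `[[`, 0, "density")
  dvec <- vapply(mat_at, function(m) diffusivity(m, frequency_hz), 0)
  bvec <- vapply(mat_at, `[[`, 0, "nonlinearity")
  dt <- cfl * dx_mm * 1e-3 / max(cvec)
  while (max(dvec) > 0 &&
         (max(cvec) * dt / (dx_mm * 1e-3))^2 +
           2 * max(dvec) * dt / (dx_mm * 1e-3)^2 > 0.9)
    dt <- dt * 0.85
  period <- 1 / frequency_hz
  spc <- max(2L, as.integer(round(period / dt)))
  nsteps <- as.integer(ceiling((2 * length_mm * 1e-3 / min(cvec) +
                                  n_cycles * period) / dt))
  recB0 <- nsteps - spc; recA0 <- nsteps - 2L * spc
  csim <- dispersion_tuned_c(cvec, dx_mm * 1e-3, dt, 2 * pi * frequency_hz)
  res <- fdtd_run_1d(csim, rvec, dvec, bvec, dx_mm * 1e-3, dt,
                     as.integer(round(source_mm / dx_mm)), p0,
                     2 * pi * frequency_hz, nsteps,
                     as.integer(round(probe_mm / dx_mm)),
                     recA0, recB0, recB0, nsteps, nonlinear,
                     source == "soft", 1e12)
  list(x_mm = x, amplitude = pmax(res$ampA, res$ampB), probes = res$probes,
       dt_s = dt, steps_per_cycle = spc,
       alpha_np_m = absorption_at(background, frequency_hz))
}

#' Dispersion-tuned simulation sound speed
#'
#' The 2nd-order stencils used by the solver propagate waves slightly slower
#' than the physical sound speed (by up to ~10 % at four points per
#' wavelength).  Because the isotropic stencils make this error
#' direction-independent, rescaling each material sound speed by the inverse
#' of the axial dispersion factor makes the numerical phase speed at the
#' drive frequency match the physical one:
#' `c_sim = dx sin(omega dt / 2) / (dt sin(omega dx / (2 c)))`.
#' The solver compensates densities inversely so that acoustic impedances
#' (and with them interface transmission) stay physical.
#'
#' @param c_phys Physical sound speed(s) (m/s).
#' @param dx_m Spatial step (m).
#' @param dt_s Time step (s).
#' @param omega Angular drive frequency (rad/s).
#' @return Tuned speed(s), same shape as `c_phys`.
#' @export
dispersion_tuned_c <- function(c_phys, dx_m, dt_s, omega) {
  arg <- omega * dx_m / (2 * c_phys)
  if (any(arg >= pi / 2))
    abort("grid too coarse: fewer than 2 points per wavelength")
  out <- dx_m * sin(omega * dt_s / 2) / (dt_s * sin(arg))
  out[arg < 1e-12] <- c_phys[arg < 1e-12]
  out
}
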