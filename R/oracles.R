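#' Closed-form on-axis field of a focused bowl (O'Neil solution)
#'
#' Linear, lossless on-axis pressure amplitude of a uniformly driven
#' spherically curved radiator.  The annular aperture (central hole) is
#' handled by superposition: outer cap minus inner cap, both sharing the
#' same curvature centre.  At the geometric centre the finite limit
#' `|p| = p0 k h` (h = cap depth) is used.  Valid for a homogeneous
#' lossless medium and linear propagation only.
#'
#' @param transducer A [transducer()]; its `surface_pressure_pa` scales the
#'   result.
#' @param medium A [material()] (only the sound speed enters).
#' @param z_mm Axial positions (mm from the bowl apex).
#' @return A tibble with `z_mm`, `amplitude_pa`, and `gain`
#'   (`amplitude_pa / p0`).
#' @export
oneil_axial <- function(transducer, medium, z_mm) {
  k <- transducer$omega / medium$sound_speed            # 1/m
  Fm <- transducer$focal_length_mm * 1e-3
  zm <- z_mm * 1e-3
  cap <- function(a_mm) {
    if (a_mm <= 0) return(rep(0 + 0i, length(zm)))
    am <- a_mm * 1e-3
    h <- Fm - sqrt(Fm^2 - am^2)
    d <- sqrt(am^2 + (zm - h)^2)                        # distance to rim
    E <- complex(real = 0, imaginary = 0) * zm
    sing <- abs(Fm - zm) < 1e-9
    E[!sing] <- Fm / (Fm - zm[!sing]) *
      (exp(-1i * k * zm[!sing]) - exp(-1i * k * d[!sing]))
    costh <- sqrt(Fm^2 - am^2) / Fm
    E[sing] <- 1i * k * Fm * (1 - costh) * exp(-1i * k * Fm)
    E
  }
  E <- cap(transducer$aperture_mm / 2) - cap(transducer$hole_mm / 2)
  tibble(z_mm = z_mm,
         amplitude_pa = transducer$surface_pressure_pa * Mod(E),
         gain = Mod(E))
}

#' On-axis field by direct Rayleigh-integral quadrature
#'
#' Independent cross-check of [oneil_axial()]: numerically integrates the
#' Rayleigh integral over the spherical cap (colatitude parametrisation) for
#' each axial point.  Agrees with the closed form to ~0.1 % away from the
#' singular point.
#'
#' @inheritParams oneil_axial
#' @return A tibble with `z_mm` and `gain`.
#' @export
rayleigh_axial <- function(transducer, medium, z_mm) {
  k <- transducer$omega / medium$sound_speed
  Fm <- transducer$focal_length_mm * 1e-3
  th_out <- asin((transducer$aperture_mm / 2 * 1e-3) / Fm)
  th_in <- if (transducer$hole_mm > 0)
    asin((transducer$hole_mm / 2 * 1e-3) / Fm) else 0
  gain <- vapply(z_mm * 1e-3, function(z) {
    Rr <- function(th) sqrt((Fm * sin(th))^2 + (z - Fm * (1 - cos(th)))^2)
    re <- integrate(function(th) sin(th) * cos(k * Rr(th)) / Rr(th),
                    th_in, th_out, rel.tol = 1e-9)$value
    im <- integrate(function(th) sin(th) * sin(k * Rr(th)) / Rr(th),
                    th_in, th_out, rel.tol = 1e-9)$value
    k * Fm^2 * sqrt(re^2 + im^2)
  }, 0)
  tibble(z_mm = z_mm, gain = gain)
}

#' Plane-wave attenuation factor
#'
#' Amplitude ratio `exp(-alpha * distance)` after propagating `distance`
#' through a medium with amplitude absorption `alpha`.
#'
#' @param alpha_np_m Amplitude absorption (Np/m), >= 0.
#' @param distance_m Path length (m), >= 0.
#' @return The amplitude ratio in (0, 1].
#' @export
plane_wave_decay <- function(alpha_np_m, distance_m) {
  stopifnot(alpha_np_m >= 0, distance_m >= 0)
  exp(-alpha_np_m * distance_m)
}

#' Normal-incidence pressure transmission at an interface
#'
#' `T = 2 Z2 / (Z1 + Z2)` with `Z = rho c`, for a wave running from medium 1
#' into medium 2.
#'
#' @param m1,m2 [material()] objects.
#' @return The pressure transmission coefficient (can exceed 1 into a
#'   stiffer medium).
#' @export
interface_transmission <- function(m1, m2) {
  z1 <- acoustic_impedance(m1); z2 <- acoustic_impedance(m2)
  stopifnot(z1 > 0, z2 > 0)
  2 * z2 / (z1 + z2)
}

#' Steady-state transmission through a lossy layer
#'
#' Exact continuous-wave pressure transmission magnitude through a uniform
#' layer of medium 2 embedded in medium 1 (normal incidence), including all
#' internal reverberation (Fabry-Perot) and absorption, via the complex
#' two-interface solution with `k2 = omega/c2 - i alpha2`.  The single-pass
#' approximation `interface_transmission(m1,m2) *
#' interface_transmission(m2,m1) * plane_wave_decay(...)` ignores the
#' reverberation and can differ by ~10 % for weakly absorbing layers.
#'
#' @param m1 Surrounding medium.
#' @param m2 Layer medium.
#' @param thickness_mm Layer thickness.
#' @param frequency_hz Drive frequency.
#' @return Transmitted/incident pressure amplitude magnitude.
#' @export
layer_transmission <- function(m1, m2, thickness_mm, frequency_hz) {
  omega <- 2 * pi * frequency_hz
  d <- thickness_mm * 1e-3
  z1 <- acoustic_impedance(m1); z2 <- acoustic_impedance(m2)
  k2 <- omega / m2$sound_speed - 1i * absorption_at(m2, frequency_hz)
  E <- exp(-1i * k2 * d)
  # unknowns: r (reflected), A, B (layer), t (transmitted, phase-referenced)
  Am <- rbind(c(-1,       1,      1,      0),
              c(1 / z1,   1 / z2, -1 / z2, 0),
              c(0,        E,      1 / E,  -1),
              c(0,        E / z2, -1 / (E * z2), -1 / z1))
  bv <- c(1, 1 / z1, 0, 0)
  sol <- solve(Am, bv + 0i)
  Mod(sol[4])
}

#' Fubini harmonic amplitudes for a nonlinear plane wave
#'
#' Pre-shock normalized harmonic amplitude `B_n = 2 J_n(n sigma)/(n sigma)`
#' of an initially sinusoidal plane wave at shock parameter
#' `sigma = x / x_shock` (`x_shock = rho c^3 / (beta omega p0)`).
#'
#' @param sigma Shock parameter, in (0, 1).
#' @param n Harmonic number (1 = fundamental).
#' @return The amplitude of harmonic `n` relative to the source amplitude.
#' @export
fubini_harmonics <- function(sigma, n) {
  if (any(sigma >= 1)) abort("Fubini solution only valid for sigma < 1")
  if (any(sigma <= 0)) abort("sigma must be > 0")
  2 * besselJ(n * sigma, n) / (n * sigma)
}
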