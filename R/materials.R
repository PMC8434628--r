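#' Acoustic material
#'
#' A homogeneous fluid medium described by the four parameters entering the
#' Westervelt equation: density, sound speed, small-signal absorption and the
#' coefficient of nonlinearity.  Absorption is given as an amplitude
#' coefficient at 1 MHz (Np/m/MHz) and scaled linearly with frequency.
#'
#' @param density Mass density (kg/m^3), > 0.
#' @param sound_speed Small-signal sound speed (m/s), > 0.
#' @param absorption Amplitude absorption coefficient (Np/m per MHz), >= 0.
#' @param nonlinearity Coefficient of nonlinearity beta (dimensionless), >= 0.
#' @param label Optional name used in printing and sweep tables.
#'
#' @return An object of class `fus_material` (a named list).
#' @examples
#' material(998.2, 1482, absorption = 0.02, nonlinearity = 3.5, label = "water")
#' @export
material <- function(density, sound_speed, absorption = 0,
                     nonlinearity = 0, label = NULL) {
  stopifnot(is.numeric(density), length(density) == 1L,
            is.numeric(sound_speed), length(sound_speed) == 1L)
  if (density <= 0) abort("`density` must be > 0")
  if (sound_speed <= 0) abort("`sound_speed` must be > 0")
  if (absorption < 0) abort("`absorption` must be >= 0")
  if (nonlinearity < 0) abort("`nonlinearity` must be >= 0")
  structure(
    list(density = density, sound_speed = sound_speed,
         absorption = absorption, nonlinearity = nonlinearity,
         label = label %||% "material"),
    class = "fus_material")
}

#' @export
print.fus_material <- function(x, ...) {
  cat(sprintf(
    "<fus_material: %s>  rho = %g kg/m^3, c = %g m/s, alpha0 = %g Np/m/MHz, beta = %g\n",
    x$label, x$density, x$sound_speed, x$absorption, x$nonlinearity))
  invisible(x)
}

#' Reference media: degassed water and acrylic (skull phantom)
#'
#' Default simulation media: degassed water as the propagation background and
#' cast acrylic for the curved skull-mimicking plates.
#'
#' @return A `fus_material`.
#' @export
water_material <- function() {
  material(998.2, 1482, absorption = 0.02, nonlinearity = 3.5, label = "water")
}

#' @rdname water_material
#' @export
acrylic_material <- function() {
  material(1203, 2600, absorption = 18, nonlinearity = 4.4, label = "acrylic")
}

#' Skull-like medium defined by swept acoustic parameters
#'
#' Builds a homogeneous plate material from skull-range acoustic parameters.
#' Absorption is taken in dB/m *at the drive frequency* (the unit used for
#' skull absorption ranges) and converted internally to Np/m/MHz assuming
#' linear frequency scaling.
#'
#' @param density kg/m^3 (default 1850).
#' @param sound_speed m/s (default 3500).
#' @param absorption_db_m Amplitude absorption in dB/m at `frequency_hz`
#'   (default 2600).
#' @param frequency_hz Frequency at which `absorption_db_m` applies
#'   (default 0.9 MHz).
#' @param nonlinearity beta (default 4.4, as for acrylic).
#' @return A `fus_material`.
#' @export
skull_material <- function(density = 1850, sound_speed = 3500,
                           absorption_db_m = 2600, frequency_hz = 0.9e6,
                           nonlinearity = 4.4) {
  alpha_np <- db_to_np(absorption_db_m)            # Np/m at frequency_hz
  material(density, sound_speed,
           absorption = alpha_np / (frequency_hz / 1e6),
           nonlinearity = nonlinearity, label = "skull-like")
}

#' Unit conversions and derived acoustic quantities
#'
#' `db_to_np()`/`np_to_db()` convert amplitude attenuation between dB and
#' neper scales (1 Np = 8.686 dB).  `absorption_at()` evaluates a material's
#' amplitude absorption (Np/m) at a frequency, assuming the linear-in-frequency
#' scaling of its Np/m/MHz coefficient.  `acoustic_impedance()` returns the
#' characteristic impedance rho*c (Pa s/m).  `diffusivity()` converts
#' absorption to the thermoviscous diffusivity of the Westervelt loss term,
#' `delta = 2 alpha c^3 / omega^2` (m^2/s), at the given frequency.
#'
#' @param x Value in dB (for `db_to_np`) or Np (for `np_to_db`).
#' @param m A `fus_material`.
#' @param frequency_hz Frequency in Hz.
#' @return A numeric scalar.
#' @examples
#' absorption_at(acrylic_material(), 0.9e6)   # 16.2 Np/m
#' diffusivity(water_material(), 0.9e6)       # ~3.66e-6 m^2/s
#' @export
db_to_np <- function(x) x / (20 / log(10))   # 8.685890 dB per Np

#' @rdname db_to_np
#' @export
np_to_db <- function(x) x * (20 / log(10))

#' @rdname db_to_np
#' @export
absorption_at <- function(m, frequency_hz) {
  m$absorption * (frequency_hz / 1e6)
}

#' @rdname db_to_np
#' @export
acoustic_impedance <- function(m) m$density * m$sound_speed

#' @rdname db_to_np
#' @export
diffusivity <- function(m, frequency_hz) {
  omega <- 2 * pi * frequency_hz
  2 * absorption_at(m, frequency_hz) * m$sound_speed^3 / omega^2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
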