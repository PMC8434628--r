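#' Locate the focal peak of an amplitude field
#'
#' Finds the arg-max of the steady-state amplitude, optionally restricted to
#' `z >= z_min_mm` (used to exclude the source region and plate interior when
#' the focus is weak).  The axial position is refined by a three-point
#' parabolic interpolation of the on-peak axial profile; ties break toward
#' smaller z.
#'
#' @param field A `fus_field`.
#' @param z_min_mm Lower edge of the axial search window (mm).
#' @return A one-row tibble: `z_mm`, `r_mm`, `peak_pa`.
#' @export
find_focus <- function(field, z_min_mm = 0) {
  g <- field$grid
  amp <- field$amplitude
  if (g$mode == "3d") {   # collapse to (r, z) by taking the transverse max
    amp <- apply(amp, 3, max)
    amp <- matrix(amp, nrow = 1)
    roff <- 0
  }
  jmin <- which(g$z_mm >= z_min_mm)[1]
  if (is.na(jmin)) abort("empty search window")
  sub <- amp[, jmin:ncol(amp), drop = FALSE]
  pk <- max(sub)
  if (pk <= 0) abort("flat-field error: amplitude has no positive peak",
                     class = "fus_flat_field")
  near <- sum(sub >= pk * (1 - 1e-9))
  if (near > 0.25 * length(sub))
    abort("flat-field error: peak not unique (amplitude nearly uniform)",
          class = "fus_flat_field")
  idx <- arrayInd(which(sub == pk)[1], dim(sub))  # ties: smallest z first
  i <- idx[1]; j <- idx[2] + jmin - 1L
  zq <- g$z_mm[j]
  if (j > 1 && j < length(g$z_mm)) {
    a0 <- amp[i, j - 1]; a1 <- amp[i, j]; a2 <- amp[i, j + 1]
    den <- a0 - 2 * a1 + a2
    if (den < 0) zq <- zq + g$dx_mm * (a0 - a2) / (2 * den)
  }
  r_mm <- if (field$grid$mode == "3d") 0 else g$r_mm[i]
  tibble(z_mm = unname(zq), r_mm = unname(r_mm), peak_pa = unname(pk))
}

#' Axial -6 dB focal length
#'
#' Length of the contiguous on-axis interval around the focal peak where the
#' amplitude stays at or above half its on-axis peak (the pressure-amplitude
#' -6 dB convention), with linear interpolation at both ends.
#'
#' @param field A `fus_field`.
#' @param focus Optional [find_focus()] row; recomputed when missing.
#' @param z_min_mm Passed to [find_focus()].
#' @return The -6 dB axial length (mm).
#' @export
minus6db_length <- function(field, focus = NULL, z_min_mm = 0) {
  pr <- axial_profile(field)
  sel <- pr$z_mm >= z_min_mm
  z <- pr$z_mm[sel]; a <- pr$amplitude_pa[sel]
  j <- which.max(a)
  lvl <- a[j] / 2
  lo <- j
  while (lo > 1 && a[lo - 1] >= lvl) lo <- lo - 1
  hi <- j
  while (hi < length(a) && a[hi + 1] >= lvl) hi <- hi + 1
  if (lo == 1 || hi == length(a))
    abort("open-region error: -6 dB region touches the domain boundary",
          class = "fus_open_region")
  zlo <- z[lo] - (z[lo] - z[lo - 1]) * (a[lo] - lvl) / (a[lo] - a[lo - 1])
  zhi <- z[hi] + (z[hi + 1] - z[hi]) * (a[hi] - lvl) / (a[hi] - a[hi + 1])
  zhi - zlo
}

#' Relative focal-pressure drop and dB attenuation
#'
#' `percent_drop()` is `100 (1 - p/p_ref)`; `attenuation_db()` is
#' `20 log10(p_ref/p)`.  They are consistent through
#' `dB = -20 log10(1 - drop/100)`.
#'
#' @param p_ref Reference amplitude (> 0).
#' @param p Amplitude under the condition of interest.
#' @return Percent (or dB) attenuation.
#' @export
percent_drop <- function(p_ref, p) {
  stopifnot(all(p_ref > 0))
  100 * (1 - p / p_ref)
}

#' @rdname percent_drop
#' @export
attenuation_db <- function(p_ref, p) {
  stopifnot(all(p_ref > 0), all(p > 0))
  20 * log10(p_ref / p)
}

#' Full focal-metric summary of a field
#'
#' @param field A `fus_field`.
#' @param z_min_mm Axial search window lower edge (mm).
#' @param p_ref_pa Optional reference peak; adds `percent_drop` and
#'   `attenuation_db` columns relative to it.
#' @return A one-row tibble: focal position, peak (Pa and kPa), -6 dB axial
#'   length, steady-state residual, and optional attenuation columns.
#' @export
focal_metrics <- function(field, z_min_mm = 0, p_ref_pa = NULL) {
  fo <- find_focus(field, z_min_mm)
  len <- tryCatch(minus6db_length(field, fo, z_min_mm),
                  fus_open_region = function(e) NA_real_)
  out <- dplyr::mutate(fo,
                       peak_kpa = .data$peak_pa / 1e3,
                       minus6db_mm = len,
                       residual = field$residual)
  if (!is.null(p_ref_pa))
    out <- dplyr::mutate(out,
                         percent_drop = percent_drop(p_ref_pa, .data$peak_pa),
                         attenuation_db = attenuation_db(p_ref_pa, .data$peak_pa))
  out
}

#' Calibrate the source amplitude to a target focal pressure
#'
#' Finds the bowl surface-pressure amplitude for which the pure-water focal
#' peak equals `target_pa`.  In linear mode the field is exactly proportional
#' to the drive, so a single run fixes the scale; with the quadratic term on,
#' one fixed-point refinement is applied.
#'
#' @param scene A [scene()] (its plate, if any, is removed for calibration).
#' @param target_pa Desired pure-water focal peak (Pa).
#' @param settings Solver settings controlling the calibration runs; the
#'   `linear` flag decides whether the refinement pass happens.
#' @return The calibrated surface pressure p0 (Pa).
#' @export
calibrate_source <- function(scene, target_pa,
                             settings = solver_settings(linear = TRUE)) {
  if (target_pa < 0) abort("`target_pa` must be >= 0")
  if (target_pa == 0) return(0)
  sc <- scene
  sc$plate <- NULL
  lin <- settings; lin$linear <- TRUE
  fld <- run_to_steady(sc, lin)
  gain <- find_focus(fld)$peak_pa / sc$transducer$surface_pressure_pa
  p0 <- target_pa / gain
  if (!settings$linear) {
    sc$transducer$surface_pressure_pa <- p0
    fld2 <- run_to_steady(sc, settings)
    p0 <- p0 * target_pa / find_focus(fld2)$peak_pa
  }
  p0
}
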