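#' Canonical sweep value lists
#'
#' The six single-parameter ranges studied with the skull-plate model:
#' structural (plate thickness 2:4:22 mm, curvature radius 60:10:100 mm,
#' standoff distance 11:1:20 mm, acrylic plate) and acoustic (density
#' 1700:30:2000 kg/m^3, sound speed 2000:300:5000 m/s, absorption
#' 200:480:5000 dB/m, skull-like plate at T8/R60/D10).  The `combined` sweep
#' pairs equal-index values of the three acoustic lists.
#'
#' @param parameter One of `"thickness"`, `"curvature"`, `"distance"`,
#'   `"density"`, `"speed"`, `"absorption"`, `"combined"`.
#' @return Numeric vector of sweep values (indices for `"combined"`).
#' @export
sweep_values <- function(parameter) {
  switch(parameter,
    thickness  = seq(2, 22, by = 4),
    curvature  = seq(60, 100, by = 10),
    distance   = seq(11, 20, by = 1),
    density    = seq(1700, 2000, by = 30),
    speed      = seq(2000, 5000, by = 300),
    absorption = seq(200, 5000, by = 480),
    combined   = seq_len(11),
    abort(sprintf("unknown sweep parameter '%s'", parameter)))
}

sweep_units <- c(thickness = "mm", curvature = "mm", distance = "mm",
                 density = "kg/m^3", speed = "m/s", absorption = "dB/m",
                 combined = "index")

#' Define a parameter sweep
#'
#' A sweep varies one plate parameter (or the combined acoustic triple) while
#' all others stay at their fixed defaults: acrylic plate T = 8 mm,
#' R = 60 mm, D = 10 mm for structural sweeps; skull-like plate
#' (rho = 1850 kg/m^3, c = 3500 m/s, alpha = 2600 dB/m) on the same geometry
#' for acoustic sweeps.
#'
#' @param parameter Swept parameter name, see [sweep_values()].
#' @param values Strictly increasing value list; defaults to the canonical
#'   range.
#' @param transducer Drive transducer (carrying the calibrated surface
#'   pressure).
#' @param water Background medium.
#' @param resolution Grid preset for each solve.
#' @param plate_material Material used for structural sweeps.
#' @param fixed Named list of fixed plate geometry
#'   (`thickness_mm`, `curvature_radius_mm`, `standoff_mm`).
#' @param acoustic_fixed Named list of fixed acoustic values
#'   (`density`, `speed`, `absorption_db_m`).
#' @param domain_mm Domain extents passed to [scene()].
#' @return An object of class `fus_sweep_spec`.
#' @export
sweep_spec <- function(parameter, values = NULL,
                       transducer = tfusim::transducer(),
                       water = water_material(),
                       resolution = "coarse",
                       plate_material = acrylic_material(),
                       fixed = list(thickness_mm = 8, curvature_radius_mm = 60,
                                    standoff_mm = 10),
                       acoustic_fixed = list(density = 1850, speed = 3500,
                                             absorption_db_m = 2600),
                       domain_mm = c(r = 50, z = 100)) {
  values <- values %||% sweep_values(parameter)
  if (length(values) == 0) abort("empty value list")
  if (is.unsorted(values, strictly = TRUE))
    abort("sweep values must be strictly increasing")
  structure(list(parameter = parameter, values = values,
                 transducer = transducer, water = water,
                 resolution = resolution, plate_material = plate_material,
                 fixed = fixed, acoustic_fixed = acoustic_fixed,
                 domain_mm = domain_mm),
            class = "fus_sweep_spec")
}

combined_triples <- function() {
  tibble(index = seq_len(11),
         density = sweep_values("density")[1:11],
         speed = sweep_values("speed")[1:11],
         absorption_db_m = sweep_values("absorption")[1:11])
}

scene_for_value <- function(spec, v) {
  fx <- spec$fixed; ac <- spec$acoustic_fixed
  f <- spec$transducer$frequency_hz
  plate <- switch(spec$parameter,
    thickness = plate_spec(v, fx$curvature_radius_mm, fx$standoff_mm,
                           spec$plate_material),
    curvature = plate_spec(fx$thickness_mm, v, fx$standoff_mm,
                           spec$plate_material),
    distance  = plate_spec(fx$thickness_mm, fx$curvature_radius_mm, v,
                           spec$plate_material),
    density   = plate_spec(fx$thickness_mm, fx$curvature_radius_mm,
                           fx$standoff_mm,
                           skull_material(v, ac$speed, ac$absorption_db_m, f)),
    speed     = plate_spec(fx$thickness_mm, fx$curvature_radius_mm,
                           fx$standoff_mm,
                           skull_material(ac$density, v, ac$absorption_db_m, f)),
    absorption = plate_spec(fx$thickness_mm, fx$curvature_radius_mm,
                            fx$standoff_mm,
                            skull_material(ac$density, ac$speed, v, f)),
    combined  = {
      tr <- combined_triples()[v, ]
      plate_spec(fx$thickness_mm, fx$curvature_radius_mm, fx$standoff_mm,
                 skull_material(tr$density, tr$speed, tr$absorption_db_m, f))
    })
  scene(spec$transducer, plate = plate, water = spec$water,
        resolution = spec$resolution, domain_mm = spec$domain_mm)
}

#' Run a parameter sweep
#'
#' One steady-state solve and focal-metric extraction per sweep value.  The
#' focal search window starts 2 mm behind the plate's back face so that
#' standing waves inside and near the plate are never mistaken for the focus
#' when the true focal region is strongly attenuated.  Per-value failures
#' are recorded (`NA` metrics) and the sweep continues.
#'
#' @param spec A [sweep_spec()].
#' @param settings [solver_settings()] used for every solve.
#' @return A tibble (class `fus_sweep`): one row per value with the swept
#'   `value`, focal metrics, and `percent_drop` / `attenuation_db` relative
#'   to the first value.  For the combined sweep the three acoustic values
#'   are included as columns.
#' @export
run_sweep <- function(spec, settings = solver_settings()) {
  rows <- purrr::map(spec$values, function(v) {
    res <- tryCatch({
      sc <- scene_for_value(spec, v)
      fld <- run_to_steady(sc, settings)
      zb <- plate_front_mm(sc) + sc$plate$thickness_mm + 2
      dplyr::bind_cols(tibble(value = v), focal_metrics(fld, z_min_mm = zb))
    }, error = function(e) {
      warning(sprintf("sweep value %g failed: %s", v, conditionMessage(e)),
              call. = FALSE)
      tibble(value = v, z_mm = NA_real_, r_mm = NA_real_,
             peak_pa = NA_real_, peak_kpa = NA_real_,
             minus6db_mm = NA_real_, residual = NA_real_)
    })
    res
  })
  out <- dplyr::bind_rows(rows)
  ref <- out$peak_pa[which(!is.na(out$peak_pa))[1]]
  out$percent_drop <- percent_drop(ref, out$peak_pa)
  out$attenuation_db <- NA_real_
  ok <- !is.na(out$peak_pa) & out$peak_pa > 0
  out$attenuation_db[ok] <- attenuation_db(ref, out$peak_pa[ok])
  if (spec$parameter == "combined")
    out <- dplyr::left_join(out, combined_triples(),
                            by = c(value = "index"))
  structure(out, parameter = spec$parameter,
            unit = sweep_units[[spec$parameter]],
            spec = spec,
            class = c("fus_sweep", class(out)))
}

#' Total percent drop across a sweep
#'
#' `100 (1 - p_last / p_first)` between the first and last (or a chosen)
#' sweep value, the convention used to summarise each sweep range.
#'
#' @param sweep A [run_sweep()] result.
#' @param at Optional swept value at which to evaluate the drop (defaults to
#'   the last value).
#' @return Percent drop relative to the first sweep value.
#' @export
sweep_total_drop <- function(sweep, at = NULL) {
  p <- sweep$peak_pa
  ref <- p[which(!is.na(p))[1]]
  idx <- if (is.null(at)) max(which(!is.na(p))) else which(sweep$value == at)
  if (length(idx) != 1 || is.na(p[idx]))
    abort("requested sweep value missing or failed")
  percent_drop(ref, p[idx])
}

#' @export
print.fus_sweep <- function(x, ...) {
  cat(sprintf("<fus_sweep: %s [%s]> %d values\n",
              attr(x, "parameter"), attr(x, "unit"), nrow(x)))
  NextMethod()
}
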