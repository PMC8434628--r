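#' Read and write scene configurations as YAML
#'
#' Scenes serialize to a YAML mapping with SI-suffixed keys.  Required
#' blocks: `transducer` (frequency_hz, aperture_mm, focal_length_mm,
#' hole_mm, surface_pressure_pa) and `water` (density_kg_m3, sound_speed_m_s,
#' absorption_np_m_mhz, nonlinearity); optional `plate` (thickness_mm,
#' curvature_radius_mm, standoff_mm, material) and `grid`
#' (resolution preset or explicit dx_mm/dt_ns), `domain` (r_mm, z_mm).
#'
#' @param scene A [scene()].
#' @param path File path.
#' @return `read_scene_yaml()` returns a `fus_scene`;
#'   `write_scene_yaml()` returns `path` invisibly.
#' @export
write_scene_yaml <- function(scene, path) {
  mat <- function(m) list(density_kg_m3 = m$density,
                          sound_speed_m_s = m$sound_speed,
                          absorption_np_m_mhz = m$absorption,
                          nonlinearity = m$nonlinearity,
                          label = m$label)
  cfg <- list(
    transducer = scene$transducer[c("frequency_hz", "aperture_mm",
                                    "focal_length_mm", "hole_mm",
                                    "surface_pressure_pa")],
    water = mat(scene$water),
    domain = list(r_mm = unname(max(scene$grid$z_mm) * 0 +
                                  if (scene$grid$mode == "axisymmetric")
                                    max(scene$grid$r_mm) else max(scene$grid$x_mm)),
                  z_mm = unname(max(scene$grid$z_mm))),
    grid = list(mode = scene$grid$mode, dx_mm = scene$grid$dx_mm,
                dt_ns = scene$grid$dt_ns))
  if (!is.null(scene$plate))
    cfg$plate <- list(thickness_mm = scene$plate$thickness_mm,
                      curvature_radius_mm = scene$plate$curvature_radius_mm,
                      standoff_mm = scene$plate$standoff_mm,
                      material = mat(scene$plate$material))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_scene_yaml
#' @export
read_scene_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- function(block, keys) {
    if (is.null(cfg[[block]]))
      abort(sprintf("config schema error: missing block '%s'", block),
            class = "fus_schema_error")
    miss <- setdiff(keys, names(cfg[[block]]))
    if (length(miss))
      abort(sprintf("config schema error: block '%s' missing key(s): %s",
                    block, paste(miss, collapse = ", ")),
            class = "fus_schema_error")
  }
  need("transducer", c("frequency_hz", "aperture_mm", "focal_length_mm",
                       "hole_mm", "surface_pressure_pa"))
  need("water", c("density_kg_m3", "sound_speed_m_s"))
  mat <- function(x) material(x$density_kg_m3, x$sound_speed_m_s,
                              x$absorption_np_m_mhz %||% 0,
                              x$nonlinearity %||% 0,
                              x$label %||% "material")
  tx <- do.call(transducer, cfg$transducer)
  plate <- if (!is.null(cfg$plate)) {
    need("plate", c("thickness_mm", "curvature_radius_mm", "standoff_mm",
                    "material"))
    plate_spec(cfg$plate$thickness_mm, cfg$plate$curvature_radius_mm,
               cfg$plate$standoff_mm, mat(cfg$plate$material))
  }
  dom <- c(r = cfg$domain$r_mm %||% 50, z = cfg$domain$z_mm %||% 100)
  if (!is.null(cfg$grid$dx_mm)) {
    water <- mat(cfg$water)
    c_max <- max(water$sound_speed,
                 if (!is.null(plate)) plate$material$sound_speed else 0)
    g <- build_grid(cfg$grid$mode %||% "axisymmetric", cfg$grid$dx_mm,
                    cfg$grid$dt_ns, dom, c_max = c_max,
                    frequency_hz = cfg$transducer$frequency_hz)
    scene(tx, plate = plate, water = water, grid = g)
  } else {
    scene(tx, plate = plate, water = mat(cfg$water),
          resolution = cfg$grid$resolution %||% "coarse", domain_mm = dom)
  }
}

#' Export a field and its axial profile to CSV
#'
#' Long-format CSV with one row per grid node (`r_mm`, `z_mm`,
#' `amplitude_pa`), and a two-column axial profile (`z_mm`, `amplitude_pa`).
#'
#' @param field A `fus_field`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(field, path) {
  write.csv(as_tibble(field), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_field_csv
#' @export
write_axial_csv <- function(field, path) {
  write.csv(axial_profile(field), path, row.names = FALSE)
  invisible(path)
}

#' Run one scene end to end from a config file
#'
#' Reads a scene YAML, solves to steady state, and writes the field CSV,
#' axial-profile CSV, metrics JSON and a run manifest into `out_dir`.
#' Deterministic: rerunning the same config reproduces the metrics JSON
#' byte for byte (timestamps live only in the manifest).
#'
#' @param config_path Scene YAML path.
#' @param out_dir Output directory (created if needed).
#' @param settings [solver_settings()].
#' @return The manifest (named list), invisibly.
#' @export
cmd_run <- function(config_path, out_dir, settings = solver_settings()) {
  sc <- read_scene_yaml(config_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fld <- run_to_steady(sc, settings)
  zmin <- if (!is.null(sc$plate))
    plate_front_mm(sc) + sc$plate$thickness_mm + 2 else 0
  met <- focal_metrics(fld, z_min_mm = zmin)
  paths <- file.path(out_dir, c("field.csv", "axial_profile.csv",
                                "metrics.json", "manifest.json"))
  write_field_csv(fld, paths[1])
  write_axial_csv(fld, paths[2])
  jsonlite::write_json(as.list(met), paths[3], auto_unbox = TRUE, digits = NA)
  manifest <- list(scene_hash = fld$provenance,
                   settings = unclass(settings),
                   package_version = as.character(utils::packageVersion("tfusim")),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   stability = as.list(check_stability(sc$grid)),
                   n_steps = fld$n_steps,
                   steady_residual = fld$residual,
                   outputs = basename(paths[1:3]))
  jsonlite::write_json(manifest, paths[4], auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Run a sweep from a config file
#'
#' The sweep YAML needs `parameter` and optionally `values`, `resolution`
#' and `surface_pressure_pa`.  Writes the per-value metrics CSV, the trend
#' fits as JSON (linear always; power law additionally for the absorption
#' sweep), and a Markdown report.
#'
#' @inheritParams cmd_run
#' @return The sweep tibble, invisibly.
#' @export
cmd_sweep <- function(config_path, out_dir, settings = solver_settings()) {
  cfg <- yaml::read_yaml(config_path)
  if (is.null(cfg$parameter))
    abort("config schema error: missing key 'parameter'",
          class = "fus_schema_error")
  tx <- transducer(surface_pressure_pa = cfg$surface_pressure_pa %||% 1e4)
  spec <- sweep_spec(cfg$parameter,
                     values = if (!is.null(cfg$values)) unlist(cfg$values),
                     transducer = tx,
                     resolution = cfg$resolution %||% "coarse")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sw <- run_sweep(spec, settings)
  write.csv(as.data.frame(sw), file.path(out_dir, "sweep.csv"),
            row.names = FALSE)
  fits <- list()
  ok <- sum(!is.na(sw$peak_kpa))
  if (ok >= 3) {
    lin <- fit_linear(sw)
    fits$linear <- list(coefficients = as.list(lin$coefficients),
                        r_squared = lin$r_squared,
                        unit_attenuation_db =
                          tryCatch(unit_attenuation(lin), error = function(e) NA))
    if (spec$parameter == "absorption" && ok >= 4) {
      pw <- fit_power(sw)
      fits$power <- list(coefficients = as.list(pw$coefficients),
                         r_squared = pw$r_squared)
    }
  } else fits$status <- "not fittable (fewer than 3 successful values)"
  jsonlite::write_json(fits, file.path(out_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(sweep_report_md(sw, fits), file.path(out_dir, "report.md"))
  invisible(sw)
}

sweep_report_md <- function(sw, fits) {
  par <- attr(sw, "parameter"); unit <- attr(sw, "unit")
  lines <- c(sprintf("# Sweep report: %s [%s]", par, unit), "",
             sprintf("| %s | peak (kPa) | z focus (mm) | -6 dB (mm) | drop (%%) | dB |",
                     par),
             "|---|---|---|---|---|---|",
             sprintf("| %g | %.2f | %.2f | %.2f | %.2f | %.3f |",
                     sw$value, sw$peak_kpa, sw$z_mm, sw$minus6db_mm,
                     sw$percent_drop, sw$attenuation_db), "")
  if (!is.null(fits$linear))
    lines <- c(lines, sprintf(
      "Linear fit: y = %.4g x + %.4g (R^2 = %.3f); unit attenuation %.3f dB per %s step.",
      fits$linear$coefficients$slope, fits$linear$coefficients$intercept,
      fits$linear$r_squared, fits$linear$unit_attenuation_db, unit))
  if (!is.null(fits$power))
    lines <- c(lines, sprintf(
      "Power fit: y = %.4g x^%.4g + %.4g (R^2 = %.3f).",
      fits$power$coefficients$a, fits$power$coefficients$b,
      fits$power$coefficients$c, fits$power$r_squared))
  if (!is.null(fits$status)) lines <- c(lines, fits$status)
  lines
}
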