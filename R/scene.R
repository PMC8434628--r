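#' Focused bowl transducer
#'
#' A single-element spherically curved (bowl) transducer with an optional
#' central circular hole, driven in continuous-wave mode with a uniform,
#' in-phase surface pressure.  Geometric focusing comes from the bowl
#' curvature; the geometric focus sits one focal length from the bowl apex
#' on the beam axis.
#'
#' @param frequency_hz Centre frequency (Hz).
#' @param aperture_mm Opening (outer) diameter of the bowl (mm).
#' @param focal_length_mm Radius of curvature = focal length (mm).
#' @param hole_mm Central hole diameter (mm), `0 <= hole < aperture`.
#' @param surface_pressure_pa Drive pressure amplitude on the bowl surface
#'   (Pa).  Usually set by [calibrate_source()].
#' @return An object of class `fus_transducer`.
#' @examples
#' transducer()  # the 0.9 MHz, 100/80/50 mm bowl used throughout
#' @export
transducer <- function(frequency_hz = 0.9e6, aperture_mm = 100,
                       focal_length_mm = 80, hole_mm = 50,
                       surface_pressure_pa = 1e4) {
  if (frequency_hz <= 0) abort("`frequency_hz` must be > 0")
  if (focal_length_mm <= 0) abort("`focal_length_mm` must be > 0")
  if (hole_mm < 0 || hole_mm >= aperture_mm)
    abort("need 0 <= hole_mm < aperture_mm")
  if (aperture_mm / 2 > focal_length_mm)
    abort("aperture radius cannot exceed the bowl radius of curvature")
  structure(
    list(frequency_hz = frequency_hz,
         omega = 2 * pi * frequency_hz,
         aperture_mm = aperture_mm,
         focal_length_mm = focal_length_mm,
         hole_mm = hole_mm,
         surface_pressure_pa = surface_pressure_pa),
    class = "fus_transducer")
}

#' @export
print.fus_transducer <- function(x, ...) {
  cat(sprintf(
    "<fus_transducer> %g MHz bowl, aperture %g mm, focal length %g mm, hole %g mm, p0 = %g kPa\n",
    x$frequency_hz / 1e6, x$aperture_mm, x$focal_length_mm, x$hole_mm,
    x$surface_pressure_pa / 1e3))
  invisible(x)
}

# axial depth of a spherical cap of curvature radius F and projected radius a
cap_depth_mm <- function(focal_length_mm, a_mm) {
  focal_length_mm - sqrt(focal_length_mm^2 - a_mm^2)
}

# z of the transducer rim plane ("open end"), measured from the bowl apex
open_end_mm <- function(tx) cap_depth_mm(tx$focal_length_mm, tx$aperture_mm / 2)

#' Curved skull-mimicking plate
#'
#' A spherical-shell plate of uniform thickness placed across the beam.  The
#' convex face points toward the transducer (a skull seen from outside the
#' head); the standoff distance is measured on the beam axis from the plane of
#' the transducer rim ("open end") to the nearest plate surface.
#'
#' @param thickness_mm Shell thickness T (mm), > 0.
#' @param curvature_radius_mm Outer (convex) surface curvature radius R (mm),
#'   `>= thickness_mm`.
#' @param standoff_mm Distance D (mm) from the transducer open end to the
#'   convex face on the axis, >= 0.
#' @param material Plate medium, a [material()]; default [acrylic_material()].
#' @return An object of class `fus_plate`.
#' @export
plate_spec <- function(thickness_mm = 8, curvature_radius_mm = 60,
                       standoff_mm = 10, material = acrylic_material()) {
  if (thickness_mm <= 0) abort("`thickness_mm` must be > 0")
  if (curvature_radius_mm < thickness_mm)
    abort("`curvature_radius_mm` must be >= `thickness_mm`")
  if (standoff_mm < 0) abort("`standoff_mm` must be >= 0")
  stopifnot(inherits(material, "fus_material"))
  structure(
    list(thickness_mm = thickness_mm,
         curvature_radius_mm = curvature_radius_mm,
         standoff_mm = standoff_mm,
         material = material),
    class = "fus_plate")
}

#' Simulation grid
#'
#' A uniform finite-difference grid, axisymmetric (r, z half-plane with the
#' beam axis at r = 0) or full 3-D.  z = 0 is the bowl apex and the beam runs
#' along +z.  Nodes sit at integer multiples of `dx_mm`.  Construction fails
#' if the time step violates the Courant bound
#' `dt <= dx / (c_max sqrt(d))` for the fastest declared medium.
#'
#' @param mode `"axisymmetric"` or `"3d"`.
#' @param dx_mm Spatial step (mm).
#' @param dt_ns Time step (ns).
#' @param extent_mm Named numeric: `c(r=, z=)` for axisymmetric (r is the
#'   radial half-extent), `c(x=, y=, z=)` for 3-D (x/y full widths, centred
#'   on the axis).
#' @param c_max Fastest sound speed the grid must be stable for (m/s).
#' @param frequency_hz Optional drive frequency; when given, the grid records
#'   whether `dx <= lambda_water/8` (the fine-resolution reference).
#' @return An object of class `fus_grid` with node coordinate vectors (mm).
#' @export
build_grid <- function(mode = c("axisymmetric", "3d"), dx_mm, dt_ns,
                       extent_mm = c(r = 50, z = 100), c_max = 1482,
                       frequency_hz = NULL) {
  mode <- match.arg(mode)
  if (dx_mm <= 0 || dt_ns <= 0) abort("`dx_mm` and `dt_ns` must be > 0")
  if (any(extent_mm <= 0)) abort("grid extents must be > 0")
  d <- if (mode == "3d") 3 else 2
  dt_max_ns <- dx_mm * 1e-3 / (c_max * sqrt(d)) * 1e9
  if (dt_ns > dt_max_ns)
    abort(sprintf(
      "invalid-config: dt = %.3g ns exceeds the stability bound %.3g ns (c_max = %g m/s)",
      dt_ns, dt_max_ns, c_max), class = "fus_invalid_config")
  g <- list(mode = mode, dx_mm = dx_mm, dt_ns = dt_ns,
            extent_mm = extent_mm, c_max = c_max,
            dt_max_ns = dt_max_ns)
  ax <- function(ext) (0:ceiling(ext / dx_mm - 1e-9)) * dx_mm
  if (mode == "axisymmetric") {
    g$r_mm <- ax(extent_mm[["r"]])
    g$z_mm <- ax(extent_mm[["z"]])
    g$dims <- c(length(g$r_mm), length(g$z_mm))
  } else {
    hx <- ax(extent_mm[["x"]] / 2); hy <- ax(extent_mm[["y"]] / 2)
    g$x_mm <- c(-rev(hx[-1]), hx)
    g$y_mm <- c(-rev(hy[-1]), hy)
    g$z_mm <- ax(extent_mm[["z"]])
    g$dims <- c(length(g$x_mm), length(g$y_mm), length(g$z_mm))
  }
  if (!is.null(frequency_hz)) {
    lambda8 <- 1482 / frequency_hz / 8 * 1e3
    g$dx_le_lambda8 <- dx_mm <= lambda8 + 1e-12
  }
  structure(g, class = "fus_grid")
}

#' @export
print.fus_grid <- function(x, ...) {
  cat(sprintf("<fus_grid %s> dx = %g mm, dt = %g ns, %s nodes\n",
              x$mode, x$dx_mm, x$dt_ns, paste(x$dims, collapse = " x ")))
  invisible(x)
}

#' Simulation scene
#'
#' Bundles the transducer, background water, optional plate, and grid into a
#' fully specified simulation.  When `grid` is omitted it is built from a
#' resolution preset: `"paper"` (dx = lambda_water/8 = 0.2 mm at 0.9 MHz),
#' `"coarse"` (lambda/4, the sweep default), or `"ci"` (lambda/6, meant for
#' miniature scenes).  The time step is the tightest of the Courant bound
#' (with 10 % margin), one twentieth of the drive period, and an explicit
#' loss-term bound `0.35 dx^2 / delta_max`.
#'
#' @param transducer A [transducer()].
#' @param plate A [plate_spec()] or `NULL` for pure water.
#' @param water Background medium.
#' @param resolution Preset name, used when `grid` is `NULL`.
#' @param grid A [build_grid()] result, overrides `resolution`.
#' @param domain_mm Domain half-width (r) and depth (z) in mm used with
#'   presets.
#' @param mode Grid mode used with presets.
#' @return An object of class `fus_scene`.
#' @examples
#' sc <- scene(transducer(), plate = plate_spec(), resolution = "coarse")
#' @export
scene <- function(transducer = tfusim::transducer(), plate = NULL,
                  water = water_material(),
                  resolution = c("coarse", "paper", "ci"),
                  grid = NULL, domain_mm = c(r = 50, z = 100),
                  mode = c("axisymmetric", "3d")) {
  mode <- match.arg(mode)
  stopifnot(inherits(transducer, "fus_transducer"))
  if (!is.null(plate)) stopifnot(inherits(plate, "fus_plate"))
  c_max <- max(water$sound_speed,
               if (!is.null(plate)) plate$material$sound_speed else 0)
  delta_max <- max(diffusivity(water, transducer$frequency_hz),
                   if (!is.null(plate))
                     diffusivity(plate$material, transducer$frequency_hz)
                   else 0)
  if (is.null(grid)) {
    resolution <- match.arg(resolution)
    lambda_mm <- water$sound_speed / transducer$frequency_hz * 1e3
    dx_mm <- lambda_mm / switch(resolution, paper = 8, coarse = 4, ci = 6)
    d <- if (mode == "3d") 3 else 2
    dt_s <- choose_dt(dx_mm * 1e-3, c_max, delta_max,
                      transducer$frequency_hz, d)
    ext <- if (mode == "3d")
      c(x = 2 * domain_mm[["r"]], y = 2 * domain_mm[["r"]], z = domain_mm[["z"]])
    else domain_mm
    grid <- build_grid(mode, dx_mm, dt_s * 1e9, ext, c_max = c_max,
                       frequency_hz = transducer$frequency_hz)
  } else {
    stopifnot(inherits(grid, "fus_grid"))
    if (grid$c_max < c_max)
      abort("grid was declared stable only up to a slower medium than the scene contains",
            class = "fus_invalid_config")
  }
  sc <- structure(
    list(transducer = transducer, plate = plate, water = water, grid = grid),
    class = "fus_scene")
  validate_scene(sc)
  sc
}

validate_scene <- function(sc) {
  tx <- sc$transducer
  g <- sc$grid
  zmax <- max(g$z_mm)
  rmax <- if (g$mode == "axisymmetric") max(g$r_mm) else max(g$x_mm)
  if (open_end_mm(tx) >= zmax || tx$aperture_mm / 2 > rmax + 1e-9)
    abort("geometry-error: transducer cap does not fit in the domain",
          class = "fus_geometry_error")
  if (!is.null(sc$plate)) {
    zf <- plate_front_mm(sc)
    if (zf <= open_end_mm(tx) - 1e-9)
      abort("geometry-error: plate would intersect the transducer opening plane",
            class = "fus_geometry_error")
    if (zf + sc$plate$thickness_mm >= zmax)
      abort("geometry-error: plate extends beyond the domain",
            class = "fus_geometry_error")
  }
  invisible(sc)
}

#' @export
print.fus_scene <- function(x, ...) {
  cat("<fus_scene>\n")
  print(x$transducer)
  cat(sprintf("  background: %s\n", x$water$label))
  if (is.null(x$plate)) cat("  plate: none (pure water)\n")
  else cat(sprintf("  plate: %s, T = %g mm, R = %g mm, D = %g mm\n",
                   x$plate$material$label, x$plate$thickness_mm,
                   x$plate$curvature_radius_mm, x$plate$standoff_mm))
  print(x$grid)
  invisible(x)
}

# axial position (mm from apex) where the convex plate face crosses the axis
plate_front_mm <- function(sc) open_end_mm(sc$transducer) + sc$plate$standoff_mm

#' Rasterize the plate onto the grid
#'
#' Marks every grid node whose centre lies inside the spherical shell bounded
#' by concentric spheres of radii R and R - T, centred on the beam axis so
#' that the convex face crosses the axis at `open end + D`.  Only the
#' transducer-facing hemisphere is kept, so the shell spans the whole
#' transverse extent of the domain wherever the spheres cross it.
#'
#' @param plate A [plate_spec()].
#' @param grid A [build_grid()] result.
#' @param transducer The scene transducer (fixes the open-end plane).
#' @return A logical occupancy array with the grid dimensions.
#' @export
rasterize_plate <- function(plate, grid, transducer) {
  zf <- open_end_mm(transducer) + plate$standoff_mm
  R <- plate$curvature_radius_mm
  Tn <- plate$thickness_mm
  zc <- zf + R                       # common centre of curvature on the axis
  if (grid$mode == "axisymmetric") {
    s2 <- outer(grid$r_mm^2, (grid$z_mm - zc)^2, "+")   # squared distance
    zs <- matrix(grid$z_mm, nrow = length(grid$r_mm),
                 ncol = length(grid$z_mm), byrow = TRUE)
  } else {
    rxy2 <- outer(grid$x_mm^2, grid$y_mm^2, "+")
    s2 <- outer(c(rxy2), (grid$z_mm - zc)^2, "+")
    dim(s2) <- grid$dims
    zs <- array(rep(grid$z_mm, each = prod(grid$dims[1:2])), dim = grid$dims)
  }
  mask <- s2 <= R^2 & s2 >= (R - Tn)^2 & zs <= zc
  cap <- source_nodes(transducer, grid)
  if (grid$mode == "axisymmetric") {
    if (any(mask[cbind(cap$i, cap$j)]))
      abort("geometry-error: plate shell intersects the source surface",
            class = "fus_geometry_error")
  } else if (any(mask[cap$lin]))
    abort("geometry-error: plate shell intersects the source surface",
          class = "fus_geometry_error")
  mask
}

#' Per-cell medium coefficient maps
#'
#' Paints each grid cell with exactly one material (plate where the occupancy
#' mask is true, water elsewhere) and derives the thermoviscous diffusivity
#' `delta = 2 alpha c^3 / omega^2` from the absorption at the drive frequency.
#'
#' @param scene A [scene()].
#' @return A list of numeric arrays `c`, `rho`, `delta`, `beta` (grid dims)
#'   plus the logical `plate_mask`, class `fus_medium_maps`.
#' @export
build_medium_maps <- function(scene) {
  g <- scene$grid
  f <- scene$transducer$frequency_hz
  shape <- if (g$mode == "axisymmetric") g$dims else g$dims
  fill <- function(w, p) {
    a <- array(w, dim = shape)
    if (!is.null(scene$plate)) a[mask] <- p
    a
  }
  mask <- if (!is.null(scene$plate))
    rasterize_plate(scene$plate, g, scene$transducer)
  else array(FALSE, dim = shape)
  w <- scene$water
  p <- scene$plate$material
  maps <- list(
    c     = fill(w$sound_speed, p$sound_speed),
    rho   = fill(w$density, p$density),
    delta = fill(diffusivity(w, f),
                 if (!is.null(p)) diffusivity(p, f) else 0),
    beta  = fill(w$nonlinearity, p$nonlinearity),
    plate_mask = mask)
  structure(maps, class = "fus_medium_maps")
}

#' Rasterized bowl source
#'
#' Projects the spherical cap (minus the central hole) onto the grid: for
#' every transverse node inside the annular aperture the cap surface
#' `z(r) = F - sqrt(F^2 - r^2)` is rounded to the nearest axial node.  All
#' cap nodes are driven in phase with the surface pressure amplitude.
#'
#' @inheritParams rasterize_plate
#' @return A tibble of node indices (1-based `i`,`j` for axisymmetric grids,
#'   plus a linear index `lin` for 3-D) with node coordinates in mm, and the
#'   drive parameters as attributes `amplitude_pa` and `omega`.
#' @export
build_source <- function(transducer, grid) {
  out <- source_nodes(transducer, grid)
  attr(out, "amplitude_pa") <- transducer$surface_pressure_pa
  attr(out, "omega") <- transducer$omega
  out
}

source_nodes <- function(tx, grid) {
  Fmm <- tx$focal_length_mm
  a_out <- tx$aperture_mm / 2
  a_in <- tx$hole_mm / 2
  if (max(grid$z_mm) < cap_depth_mm(Fmm, a_out))
    abort("geometry-error: cap exits domain", class = "fus_geometry_error")
  if (grid$mode == "axisymmetric") {
    r <- grid$r_mm
    sel <- which(r >= a_in - 1e-9 & r <= a_out + 1e-9)
    zc <- cap_depth_mm(Fmm, pmin(r[sel], Fmm))
    j <- round(zc / grid$dx_mm) + 1L
    tibble(i = sel, j = j, r_mm = r[sel], z_mm = grid$z_mm[j],
           cap_z_mm = zc,
           cos_normal = sqrt(pmax(Fmm^2 - r[sel]^2, 0)) / Fmm)
  } else {
    nx <- grid$dims[1]; ny <- grid$dims[2]
    rxy <- sqrt(outer(grid$x_mm^2, grid$y_mm^2, "+"))
    sel <- which(rxy >= a_in - 1e-9 & rxy <= a_out + 1e-9)
    zc <- cap_depth_mm(Fmm, pmin(rxy[sel], Fmm))
    j <- round(zc / grid$dx_mm) + 1L
    ij <- arrayInd(sel, c(nx, ny))
    tibble(ix = ij[, 1], iy = ij[, 2], j = j,
           r_mm = rxy[sel], z_mm = grid$z_mm[j],
           cap_z_mm = zc,
           cos_normal = sqrt(pmax(Fmm^2 - rxy[sel]^2, 0)) / Fmm,
           lin = (j - 1L) * nx * ny + (ij[, 2] - 1L) * nx + ij[, 1])
  }
}

# Time-step selection: start from min(Courant bound with margin, T/20 drive
# sampling) and shrink until the combined von Neumann condition for the
# leapfrog + explicit thermoviscous term holds,
#   (c_sim dt/dx)^2 + 2 delta dt / dx^2 <= limit
# with limit 1/2 in 2-D and 1/3 in 3-D (worst-stencil spatial symbol), under
# a 10 % margin.  c_sim is the dispersion-tuned speed, slightly above c.
choose_dt <- function(dx_m, c_max, delta_max, frequency_hz, d) {
  period <- 1 / frequency_hz
  dt <- min(0.9 * dx_m / (c_max * sqrt(d)), period / 20)
  lim <- 0.9 * (if (d == 3) 1 / 3 else 1 / 2)
  omega <- 2 * pi * frequency_hz
  for (it in 1:40) {
    cs <- dispersion_tuned_c(c_max, dx_m, dt, omega)
    if ((cs * dt / dx_m)^2 + 2 * delta_max * dt / dx_m^2 <= lim) break
    dt <- dt * 0.85
  }
  dt
}
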