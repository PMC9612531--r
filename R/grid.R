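#' Simulation grid specification
#'
#' Describes a voxelized simulation domain: an isotropic Cartesian grid in two
#' or three dimensions with a perfectly matched layer (PML) of `pml_size`
#' voxels on every face.  The first axis is the transducer's nominal beam axis
#' at normal incidence.
#'
#' @param shape Integer vector of length 2 or 3; voxels per axis (including
#'   the PML).
#' @param spacing Isotropic voxel edge length in meters.
#' @param pml_size PML thickness in voxels per side (default 10); a scalar or
#'   one value per axis.  A 0 leaves that axis periodic (no absorbing layer),
#'   which turns a full-width line source into an exact plane wave.
#' @param pml_alpha Dimensionless PML absorption parameter (default 2).
#'
#' @return An object of class `fus_grid`.
#' @examples
#' g <- grid_spec(c(128, 128), spacing = 5e-4)
#' interior_extent(g)
#' @export
grid_spec <- function(shape, spacing, pml_size = 10L, pml_alpha = 2) {
  shape <- as.integer(shape)
  if (!length(shape) %in% c(2L, 3L)) {
    stop("`shape` must have 2 or 3 axes", call. = FALSE)
  }
  if (any(!is.finite(shape)) || any(shape < 1L)) {
    stop("`shape` entries must be positive integers", call. = FALSE)
  }
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0) {
    stop("`spacing` must be a single positive number (meters)", call. = FALSE)
  }
  pml_size <- as.integer(pml_size)
  if (!length(pml_size) %in% c(1L, length(shape))) {
    stop("`pml_size` must be a scalar or one value per axis", call. = FALSE)
  }
  pml_size <- rep_len(pml_size, length(shape))
  if (any(pml_size < 0L)) stop("`pml_size` must be >= 0", call. = FALSE)
  if (pml_alpha < 0) stop("`pml_alpha` must be >= 0", call. = FALSE)
  if (any(shape < 4L * pml_size)) {
    stop("each grid axis must span at least 4 x pml_size voxels",
         call. = FALSE)
  }
  structure(
    list(shape = shape, spacing = spacing,
         pml_size = pml_size, pml_alpha = pml_alpha),
    class = "fus_grid"
  )
}

#' Interior (non-PML) physical extent of a grid
#'
#' @param grid A [grid_spec()] object.
#' @return Numeric vector, meters per axis: `(shape - 2 * pml_size) * spacing`.
#' @export
interior_extent <- function(grid) {
  stopifnot(inherits(grid, "fus_grid"))
  (grid$shape - 2L * grid$pml_size) * grid$spacing
}

#' @export
print.fus_grid <- function(x, ...) {
  cat(sprintf("<fus_grid> %s voxels @ %.4g mm, PML %s voxels (alpha = %g)\n",
              paste(x$shape, collapse = " x "), x$spacing * 1e3,
              paste(x$pml_size, collapse = "/"), x$pml_alpha))
  cat(sprintf("  interior extent: %s mm\n",
              paste(signif(interior_extent(x) * 1e3, 4), collapse = " x ")))
  invisible(x)
}

#' Acoustic material properties
#'
#' Bundles the density, sound speed and power-law absorption of a homogeneous
#' medium.  Absorption follows `absorption_coeff * (f / 1 MHz)^absorption_power`
#' in Np/m, i.e. `absorption_coeff` is the Np.MHz^-power.m^-1 prefactor.
#'
#' @param density kg/m^3.
#' @param sound_speed m/s.
#' @param absorption_coeff Np.MHz^-power.m^-1 power-law prefactor (>= 0).
#' @param absorption_power Dimensionless frequency exponent, in \[0, 3\].
#' @return An object of class `fus_material`.
#' @seealso [water_props()], [bone_props()]
#' @export
material_props <- function(density, sound_speed, absorption_coeff = 0,
                           absorption_power = 1) {
  if (density <= 0) stop("`density` must be positive", call. = FALSE)
  if (sound_speed <= 0) stop("`sound_speed` must be positive", call. = FALSE)
  if (absorption_coeff < 0) stop("`absorption_coeff` must be >= 0", call. = FALSE)
  if (absorption_power < 0 || absorption_power > 3) {
    stop("`absorption_power` must lie in [0, 3]", call. = FALSE)
  }
  structure(
    list(density = density, sound_speed = sound_speed,
         absorption_coeff = absorption_coeff,
         absorption_power = absorption_power),
    class = "fus_material"
  )
}

#' Default water medium (body temperature)
#'
#' Density 1000 kg/m^3 and sound speed 1482 m/s; absorption is quadratic in
#' frequency with the prefactor taken from [water_absorption()] at the given
#' temperature (evaluated at 1 MHz).
#'
#' @param temperature_c Water temperature in degrees Celsius (default 37).
#' @return A `fus_material`.
#' @export
water_props <- function(temperature_c = 37) {
  material_props(
    density = 1000, sound_speed = 1482,
    absorption_coeff = water_absorption(1e6, temperature_c),
    absorption_power = 2
  )
}

#' Default bulk-bone medium
#'
#' Homogeneous bulk bone: density 1732 kg/m^3, sound speed 2850 m/s,
#' absorption 85 Np.MHz^-1.m^-1 (linear in frequency).
#'
#' @return A `fus_material`.
#' @export
bone_props <- function() {
  material_props(density = 1732, sound_speed = 2850,
                 absorption_coeff = 85, absorption_power = 1)
}

#' Evaluate a material's absorption at a carrier frequency
#'
#' @param material A [material_props()] object.
#' @param frequency Carrier frequency, Hz.
#' @return Absorption in Np/m at `frequency`.
#' @export
absorption_at <- function(material, frequency) {
  stopifnot(inherits(material, "fus_material"))
  if (frequency <= 0) stop("`frequency` must be positive", call. = FALSE)
  material$absorption_coeff * (frequency / 1e6)^material$absorption_power
}

#' Focused bowl transducer specification
#'
#' A single-element spherical-cap (bowl) transducer.  The radius of curvature
#' is derived from the focal depth and aperture radius,
#' `sqrt(focal_depth^2 + (diameter / 2)^2)`, so the geometric focus sits
#' `focal_depth` beyond the aperture plane along the beam axis.
#'
#' @param diameter Aperture (chord) diameter, m.
#' @param focal_depth Geometric focus distance from the aperture plane, m.
#' @param carrier_frequency Drive frequency, Hz.
#' @param trajectory_deg Angle between the beam axis and the bone surface in
#'   degrees; 90 is normal incidence ("flat against bone").
#' @param source_pressure Drive amplitude, Pa (default 1.0558 MPa).
#' @return An object of class `fus_transducer` with the derived
#'   `radius_of_curvature` field.
#' @examples
#' tx <- transducer_spec(diameter = 0.08, focal_depth = 0.08,
#'                       carrier_frequency = 1e6)
#' tx$radius_of_curvature
#' @export
transducer_spec <- function(diameter, focal_depth, carrier_frequency,
                            trajectory_deg = 90, source_pressure = 1.0558e6) {
  if (diameter <= 0) stop("`diameter` must be positive", call. = FALSE)
  if (carrier_frequency <= 0) {
    stop("`carrier_frequency` must be positive", call. = FALSE)
  }
  if (trajectory_deg <= 0 || trajectory_deg > 90) {
    stop("`trajectory_deg` must lie in (0, 90]", call. = FALSE)
  }
  if (source_pressure <= 0) stop("`source_pressure` must be positive", call. = FALSE)
  roc <- compute_radius_of_curvature(focal_depth, diameter / 2)
  structure(
    list(diameter = diameter, focal_depth = focal_depth,
         radius_of_curvature = roc, trajectory_deg = trajectory_deg,
         carrier_frequency = carrier_frequency,
         source_pressure = source_pressure),
    class = "fus_transducer"
  )
}

#' @export
print.fus_transducer <- function(x, ...) {
  cat(sprintf(
    paste0("<fus_transducer> diameter %.1f mm, focal depth %.1f mm ",
           "(ROC %.2f mm), %g kHz, trajectory %g deg\n"),
    x$diameter * 1e3, x$focal_depth * 1e3, x$radius_of_curvature * 1e3,
    x$carrier_frequency / 1e3, x$trajectory_deg))
  invisible(x)
}

#' Radius of curvature of a focused bowl
#'
#' For a spherical-cap transducer the defining sphere's radius follows from
#' the focal depth (aperture plane to geometric focus) and the aperture
#' radius: `sqrt(focal_depth^2 + radius^2)`.
#'
#' @param focal_depth Focal depth, m (> 0).
#' @param radius Aperture radius (= diameter / 2), m (>= 0).
#' @return Radius of curvature, m.
#' @examples
#' compute_radius_of_curvature(0.08, 0.04)
#' @export
compute_radius_of_curvature <- function(focal_depth, radius) {
  if (any(focal_depth <= 0)) {
    stop("invalid geometry: `focal_depth` must be positive", call. = FALSE)
  }
  if (any(radius < 0)) {
    stop("invalid geometry: `radius` must be >= 0", call. = FALSE)
  }
  sqrt(focal_depth^2 + radius^2)
}

# Pure-water absorption-over-frequency-squared fit: temperature (deg C) vs
# alpha / f^2 in 1e-15 Np s^2 / m, classical pure-water measurements.
.water_abs_table <- list(
  temp_c = c(0, 10, 20, 30, 40, 50, 60),
  a_f2   = c(56.9, 35.8, 25.3, 19.1, 14.6, 11.8, 10.0)
)

#' Pure-water acoustic absorption
#'
#' Classical pure-water absorption with quadratic frequency dependence:
#' `alpha = A(T) * f^2` where `A(T)` is a monotone spline through published
#' temperature measurements of `alpha / f^2` (in 1e-15 Np s^2/m).
#'
#' @param frequency Hz (> 0).
#' @param temperature_c Degrees Celsius, in (0, 60).
#' @return Absorption in Np/m.
#' @examples
#' water_absorption(1e6, 37)
#' @export
water_absorption <- function(frequency, temperature_c = 37) {
  if (any(frequency <= 0)) stop("`frequency` must be positive", call. = FALSE)
  if (any(temperature_c <= 0) || any(temperature_c >= 60)) {
    stop("`temperature_c` out of supported range (0, 60)", call. = FALSE)
  }
  fit <- stats::splinefun(.water_abs_table$temp_c, .water_abs_table$a_f2,
                          method = "hyman")
  fit(temperature_c) * 1e-15 * frequency^2
}

#' Derived grid and time-stepping metrics
#'
#' Points-per-wavelength, interior extent, time step and step count for a
#' grid / medium / solver combination.  `dt = cfl * spacing / max_speed` and
#' `n_steps = round(t_end / dt)`.
#'
#' @param grid A [grid_spec()].
#' @param medium_speed Sound speed used for the wavelength, m/s.
#' @param frequency Carrier frequency, Hz.
#' @param cfl Courant-Friedrichs-Lewy number (0 < cfl <= 1), default 0.3.
#' @param max_speed Fastest sound speed in the scene (controls `dt`);
#'   defaults to `medium_speed`.
#' @param t_end Simulated duration, s (optional; `dt`/`n_steps` need it).
#' @return List with `ppw`, `interior_extent` (m per axis), `dt` (s) and
#'   `n_steps` (NA when `t_end` is missing).
#' @examples
#' g <- grid_spec(c(256, 256, 256), 5e-4)
#' grid_metrics(g, 1482, 1e6)$ppw   # 2.964
#' @export
grid_metrics <- function(grid, medium_speed, frequency, cfl = 0.3,
                         max_speed = medium_speed, t_end = NULL) {
  stopifnot(inherits(grid, "fus_grid"))
  if (medium_speed <= 0 || frequency <= 0 || max_speed <= 0) {
    stop("speeds and frequency must be positive", call. = FALSE)
  }
  if (cfl <= 0 || cfl > 1) stop("`cfl` must lie in (0, 1]", call. = FALSE)
  dt <- cfl * grid$spacing / max_speed
  n_steps <- if (is.null(t_end)) NA_integer_ else {
    if (t_end <= 0) stop("`t_end` must be positive", call. = FALSE)
    as.integer(round(t_end / dt))
  }
  list(
    ppw = (medium_speed / frequency) / grid$spacing,
    interior_extent = interior_extent(grid),
    dt = dt,
    n_steps = n_steps
  )
}
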