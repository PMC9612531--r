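# k-space pseudospectral time-domain (PSTD) acoustic solver.
#
# First-order coupled equations (pressure via split acoustic-density
# components, particle velocity per axis) with spectral spatial derivatives
# on staggered grids, k-space dispersion correction sinc(c_ref k dt / 2),
# split-field exponential PML, and a stationary per-voxel loss evaluated at
# the carrier frequency.  No randomness anywhere: runs are bit-reproducible.

fft_freqs <- function(n, dx) {
  # angular wavenumbers in FFT order
  k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1)) * (2 * pi / (n * dx))
  k
}

sinc <- function(x) ifelse(abs(x) < 1e-12, 1, sin(x) / x)

#' Solver configuration
#'
#' @param cfl Courant-Friedrichs-Lewy number in (0, 0.5\]; `dt = cfl *
#'   spacing / max(sound speed)` (default 0.3).
#' @param t_end Simulated duration in seconds, or `NULL` to use the time a
#'   water wavefront needs to cross the interior along the beam axis
#'   (times 1.01).
#' @param ramp_cycles Carrier cycles of cosine-taper source onset (default 3);
#'   maximum-pressure recording starts after the ramp completes.
#' @param record_after Optional time (s) after which recording starts;
#'   defaults to the ramp duration.
#' @return An object of class `fus_solver_config`.
#' @export
solver_config <- function(cfl = 0.3, t_end = NULL, ramp_cycles = 3,
                          record_after = NULL) {
  if (cfl <= 0 || cfl > 0.5) stop("`cfl` must lie in (0, 0.5]", call. = FALSE)
  if (!is.null(t_end) && t_end <= 0) stop("`t_end` must be positive", call. = FALSE)
  if (ramp_cycles < 0) stop("`ramp_cycles` must be >= 0", call. = FALSE)
  structure(list(cfl = cfl, t_end = t_end, ramp_cycles = ramp_cycles,
                 record_after = record_after),
            class = "fus_solver_config")
}

# per-axis PML amplitude factor exp(-sigma dt / 2) in a vector of length n
pml_factor <- function(n, pml_size, pml_alpha, c_ref, dx, dt) {
  sigma <- numeric(n)
  if (pml_size > 0L) {
    depth_l <- pmax(0, (pml_size + 1L) - seq_len(n))   # left face
    depth_r <- pmax(0, seq_len(n) - (n - pml_size))    # right face
    depth <- pmax(depth_l, depth_r)
    sigma <- pml_alpha * (c_ref / dx) * (depth / pml_size)^4
  }
  exp(-sigma * dt / 2)
}

#' Run a time-domain acoustic simulation
#'
#' Integrates the first-order acoustic equations through the scene's
#' heterogeneous density/speed maps with spectral derivatives, k-space
#' dispersion correction and a split-field PML, driving the transducer shell
#' with an additive sinusoidal pressure source (cosine-taper onset), and
#' records the per-voxel maximum pressure after the onset ramp.
#'
#' The additive source is scaled so a plane sheet of source voxels radiates a
#' wave whose amplitude equals the drive amplitude.  The stationary loss
#' multiplies both the acoustic density components and the particle velocity
#' by `exp(-alpha c dt)` per step, which makes a travelling wave decay as
#' `exp(-alpha x)` (Beer-Lambert) at the carrier frequency.
#'
#' @param scene A [assemble_scene()] scene.
#' @param config A [solver_config()].
#' @param sensor_mask Optional logical array (grid shape) or vector of voxel
#'   indices at which the full pressure time series is recorded.
#' @return An object of class `fus_record` with fields `max_pressure`
#'   (Pa, array of `grid$shape`), `grid`, `dt`, `n_steps`, `ramp_steps`, and,
#'   when sensors were requested, `sensor_data` (steps x sensors matrix) and
#'   `sensor_index`.
#' @export
run_simulation <- function(scene, config = solver_config(),
                           sensor_mask = NULL) {
  stopifnot(inherits(scene, "fus_scene"),
            inherits(config, "fus_solver_config"))
  g <- scene$grid
  dims <- g$shape
  nd <- length(dims)
  dx <- g$spacing
  nvox <- prod(dims)

  c_map <- scene$speed_map
  c_ref <- max(c_map)
  dt <- config$cfl * dx / c_ref
  t_end <- config$t_end
  if (is.null(t_end)) {
    t_end <- 1.01 * interior_extent(g)[1L] / scene$water$sound_speed
  }
  n_steps <- max(1L, as.integer(round(t_end / dt)))

  f0 <- scene$transducer$carrier_frequency
  amp <- scene$transducer$source_pressure
  ramp_t <- config$ramp_cycles / f0
  record_after <- if (is.null(config$record_after)) ramp_t else config$record_after

  # spectral derivative operators (with staggered-grid shifts) and k-space
  # correction
  kvecs <- lapply(seq_len(nd), function(d) fft_freqs(dims[d], dx))
  karrs <- lapply(seq_len(nd), function(d) broadcast_axis(kvecs[[d]], dims, d))
  kmag <- sqrt(Reduce(`+`, lapply(karrs, function(k) k^2)))
  kappa <- sinc(c_ref * kmag * dt / 2)
  ddx_pos <- lapply(seq_len(nd), function(d) {
    (1i * karrs[[d]]) * kappa * exp(1i * karrs[[d]] * dx / 2)
  })
  ddx_neg <- lapply(seq_len(nd), function(d) {
    (1i * karrs[[d]]) * kappa * exp(-1i * karrs[[d]] * dx / 2)
  })
  rm(karrs, kmag, kappa)

  pml <- lapply(seq_len(nd), function(d) {
    broadcast_axis(
      pml_factor(dims[d], g$pml_size[min(d, length(g$pml_size))],
                 g$pml_alpha, c_ref, dx, dt),
      dims, d)
  })

  rho0 <- scene$density_map
  # density on the staggered (i + 1/2) velocity grids: neighbor average along
  # each axis, which sharpens interface accuracy for two-valued media
  shift_fwd <- function(a, d) {
    n <- dims[d]
    idx <- rep(list(quote(expr = )), nd)
    idx[[d]] <- c(2:n, n)
    do.call(`[`, c(list(a), idx))
  }
  rho0_sg <- lapply(seq_len(nd), function(d) (rho0 + shift_fwd(rho0, d)) / 2)
  abs_fac <- exp(-scene$absorption_map * c_map * dt)
  lossy <- any(scene$absorption_map > 0)
  c2 <- c_map^2

  src_idx <- which(scene$source_mask)
  if (length(src_idx) == 0L) stop("scene has an empty source mask", call. = FALSE)
  # additive source coefficient per acoustic-density component: a plane sheet
  # driven this way radiates amplitude = drive amplitude (both directions);
  # rasterized bowl shells carry a surface-density correction so the drive
  # matches the ideal one-voxel cap
  src_scale <- if (is.null(scene$source_scale)) 1 else scene$source_scale
  src_coef <- src_scale * 2 * dt / (nd * c_map[src_idx] * dx)
  # per-voxel phase offsets (rasterization correction): drive voxel k with
  # sin(w t + phi_k) = sin(w t) cos(phi_k) + cos(w t) sin(phi_k)
  src_phase <- if (is.null(scene$source_phase)) numeric(length(src_idx))
               else scene$source_phase
  src_coef_a <- src_coef * cos(src_phase)
  src_coef_b <- src_coef * sin(src_phase)

  sensor_idx <- integer(0)
  if (!is.null(sensor_mask)) {
    sensor_idx <- if (is.logical(sensor_mask)) which(sensor_mask)
                  else as.integer(sensor_mask)
  }

  t_steps <- seq_len(n_steps) * dt
  ramp <- if (ramp_t == 0) rep(1, n_steps) else {
    ifelse(t_steps >= ramp_t, 1, 0.5 * (1 - cos(pi * t_steps / ramp_t)))
  }
  signal_a <- amp * sin(2 * pi * f0 * t_steps) * ramp
  signal_b <- amp * cos(2 * pi * f0 * t_steps) * ramp
  record_start <- as.integer(floor(record_after / dt + 1e-9))

  res <- if (nd == 2L) {
    fus_kernel2(ddx_pos[[1L]], ddx_pos[[2L]], ddx_neg[[1L]], ddx_neg[[2L]],
                pml[[1L]], pml[[2L]], rho0_sg[[1L]], rho0_sg[[2L]], rho0,
                abs_fac, c2, dt, src_idx - 1L, src_coef_a, src_coef_b,
                signal_a, signal_b, record_start, sensor_idx - 1L, lossy)
  } else {
    fus_kernel3(ddx_pos[[1L]], ddx_pos[[2L]], ddx_pos[[3L]],
                ddx_neg[[1L]], ddx_neg[[2L]], ddx_neg[[3L]],
                pml[[1L]], pml[[2L]], pml[[3L]],
                rho0_sg[[1L]], rho0_sg[[2L]], rho0_sg[[3L]], rho0,
                abs_fac, c2, dt, src_idx - 1L, src_coef_a, src_coef_b,
                signal_a, signal_b, record_start, sensor_idx - 1L, lossy)
  }
  max_p <- array(res$max_pressure, dims)
  if (!all(is.finite(max_p))) {
    stop(sprintf("solver divergence: non-finite field at step %d", n_steps),
         call. = FALSE)
  }

  structure(
    list(max_pressure = max_p, grid = g, dt = dt, n_steps = n_steps,
         ramp_steps = as.integer(ceiling(ramp_t / dt)),
         transducer = scene$transducer,
         sensor_data = if (length(sensor_idx)) res$sensor_data else NULL,
         sensor_index = if (length(sensor_idx)) sensor_idx else NULL),
    class = "fus_record"
  )
}

#' @export
print.fus_record <- function(x, ...) {
  cat(sprintf("<fus_record> %s voxels, %d steps @ dt = %.3g s, max %.4g Pa\n",
              paste(x$grid$shape, collapse = " x "), x$n_steps, x$dt,
              max(x$max_pressure)))
  invisible(x)
}

#' Locate the peak intensity inside a search region
#'
#' The intensity proxy is the squared maximum pressure.  Ties are broken by
#' the lowest linear (column-major) voxel index.
#'
#' @param record A [run_simulation()] record.
#' @param search_mask Logical array of the record's grid shape; the region
#'   eligible for the search.
#' @return List with `peak_intensity` (Pa^2), `location` (m, voxel-center
#'   physical coordinates) and `index` (voxel indices).
#' @export
extract_peak <- function(record, search_mask) {
  stopifnot(inherits(record, "fus_record"))
  if (!identical(dim(search_mask), dim(record$max_pressure))) {
    stop("search mask shape does not match the record", call. = FALSE)
  }
  idx_all <- which(search_mask)
  if (length(idx_all) == 0L) stop("empty search mask", call. = FALSE)
  vals <- record$max_pressure[idx_all]
  best <- idx_all[which.max(vals)]     # first max = lowest linear index
  index <- as.integer(arrayInd(best, dim(record$max_pressure)))
  list(
    peak_intensity = max(vals)^2,
    location = (index - 0.5) * record$grid$spacing,
    index = index
  )
}

#' Extract the on-axis pressure profile of a record
#'
#' Reads the maximum-pressure values along the beam-axis line through the
#' transducer's geometric center (its untilted apex), with positions measured
#' from the back of the transducer concavity.
#'
#' @param record A [run_simulation()] record.
#' @param scene The scene that produced it.
#' @param interior_only Drop voxels inside the PML (default `TRUE`).
#' @return An [axial_profile()].
#' @export
extract_axial_profile <- function(record, scene, interior_only = TRUE) {
  stopifnot(inherits(record, "fus_record"), inherits(scene, "fus_scene"))
  g <- scene$grid
  dims <- g$shape
  apex_i <- scene$geometry$apex_index
  i_range <- if (interior_only) {
    (g$pml_size[1L] + 1L):(dims[1L] - g$pml_size[1L])
  } else seq_len(dims[1L])
  line <- if (length(dims) == 2L) {
    record$max_pressure[i_range, apex_i[2L]]
  } else {
    record$max_pressure[i_range, apex_i[2L], apex_i[3L]]
  }
  z <- (i_range - apex_i[1L]) * g$spacing
  keep <- z > 0
  axial_profile(z[keep], line[keep])
}
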