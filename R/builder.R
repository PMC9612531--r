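# Surrogate builder: sweep the 5-D parameter grid, run paired bone/water
# simulations, tabulate attenuation (%) and refraction (mm) tensors.

.axis_names <- c("frequency", "thickness", "trajectory", "depth", "diameter")

#' One point of the five-dimensional study space
#'
#' @param frequency Carrier frequency, Hz.
#' @param bone_thickness Bone layer thickness, m.
#' @param trajectory_deg Angle between beam axis and bone surface, degrees
#'   (90 = normal incidence).
#' @param focal_depth Geometric focal depth, m.
#' @param transducer_diameter Aperture diameter, m.
#' @return An object of class `fus_point`.
#' @export
parameter_point <- function(frequency, bone_thickness, trajectory_deg,
                            focal_depth, transducer_diameter) {
  vals <- c(frequency, bone_thickness, trajectory_deg, focal_depth,
            transducer_diameter)
  if (any(!is.finite(vals)) || frequency <= 0 || bone_thickness < 0 ||
      trajectory_deg <= 0 || trajectory_deg > 90 || focal_depth <= 0 ||
      transducer_diameter <= 0) {
    stop("invalid parameter point", call. = FALSE)
  }
  structure(
    list(frequency = unname(frequency), bone_thickness = unname(bone_thickness),
         trajectory_deg = unname(trajectory_deg),
         focal_depth = unname(focal_depth),
         transducer_diameter = unname(transducer_diameter)),
    class = "fus_point"
  )
}

#' @export
print.fus_point <- function(x, ...) {
  cat(sprintf(
    "<fus_point> %g kHz, bone %.1f mm, %g deg, depth %.1f mm, diameter %.1f mm\n",
    x$frequency / 1e3, x$bone_thickness * 1e3, x$trajectory_deg,
    x$focal_depth * 1e3, x$transducer_diameter * 1e3))
  invisible(x)
}

#' Five-axis parameter grid
#'
#' Axis order is fixed: frequency (Hz), thickness (m), trajectory (deg),
#' depth (m), diameter (m).  Every axis needs at least two strictly
#' increasing levels.
#'
#' @param frequency,thickness,trajectory,depth,diameter Numeric level
#'   vectors.
#' @return An object of class `fus_grid5` with a `levels` list in axis order.
#' @export
parameter_grid <- function(frequency, thickness, trajectory, depth, diameter) {
  levels <- list(frequency = frequency, thickness = thickness,
                 trajectory = trajectory, depth = depth, diameter = diameter)
  for (nm in .axis_names) {
    v <- levels[[nm]]
    if (length(v) < 2L || any(diff(v) <= 0)) {
      stop(sprintf("axis '%s' needs >= 2 strictly increasing levels", nm),
           call. = FALSE)
    }
  }
  structure(list(axes = .axis_names, levels = levels), class = "fus_grid5")
}

#' @export
print.fus_grid5 <- function(x, ...) {
  cat("<fus_grid5>", paste(vapply(x$levels, length, 1L), collapse = " x "),
      "levels:", "\n")
  for (nm in x$axes) {
    cat(sprintf("  %-10s %s\n", nm, paste(signif(x$levels[[nm]], 4),
                                          collapse = ", ")))
  }
  invisible(x)
}

#' Enumerate grid points with validity pre-flags
#'
#' Expands the full Cartesian product in row-major axis order (the first
#' axis varies slowest) and pre-flags points whose theoretical focus falls
#' inside bone (`focal_depth <= bone_thickness`) or whose geometry cannot
#' fit the simulation interior (focus outside the simulated head); flagged
#' points are skipped by the sweep.
#'
#' @param grid A [parameter_grid()].
#' @param grid_spec Optional [grid_spec()]; when given, each point's bowl
#'   and focus are checked against the interior.
#' @return Data frame with one row per point: the five parameter columns,
#'   `valid`, and `reason` (NA when valid).
#' @export
enumerate_points <- function(grid, grid_spec = NULL) {
  stopifnot(inherits(grid, "fus_grid5"))
  lv <- grid$levels
  # row-major: first axis varies slowest
  df <- expand.grid(diameter = lv$diameter, depth = lv$depth,
                    trajectory = lv$trajectory, thickness = lv$thickness,
                    frequency = lv$frequency,
                    KEEP.OUT.ATTRS = FALSE)[, rev(seq_len(5L))]
  names(df) <- .axis_names
  df$valid <- TRUE
  df$reason <- NA_character_
  inside_bone <- df$depth <= df$thickness
  df$valid[inside_bone] <- FALSE
  df$reason[inside_bone] <- "focus inside bone"
  if (!is.null(grid_spec)) {
    for (i in which(df$valid)) {
      tx <- transducer_spec(df$diameter[i], df$depth[i], df$frequency[i],
                            trajectory_deg = df$trajectory[i])
      chk <- check_geometry(grid_spec, tx, df$thickness[i])
      if (!chk$ok) {
        df$valid[i] <- FALSE
        df$reason[i] <- chk$reason
      }
    }
  }
  df
}

point_from_row <- function(row) {
  parameter_point(row$frequency, row$thickness, row$trajectory,
                  row$depth, row$diameter)
}

#' Run the bone/water simulation pair for one parameter point
#'
#' Both runs share the transducer geometry, drive, duration and search mask;
#' they differ only in whether the flat bone slab carries bone or water
#' properties.
#'
#' @param point A [parameter_point()].
#' @param solver A [solver_config()].
#' @param grid_spec A [grid_spec()].
#' @param bone,water [material_props()].
#' @return List with `bone_record`, `water_record`, `scene_bone`,
#'   `scene_water`.
#' @export
simulate_pair <- function(point, solver = solver_config(), grid_spec,
                          bone = bone_props(), water = water_props()) {
  stopifnot(inherits(point, "fus_point"))
  tx <- transducer_spec(point$transducer_diameter, point$focal_depth,
                        point$frequency, trajectory_deg = point$trajectory_deg)
  scene_bone <- assemble_scene(grid_spec, tx, point$bone_thickness,
                               with_bone = TRUE, bone = bone, water = water)
  scene_water <- assemble_scene(grid_spec, tx, point$bone_thickness,
                                with_bone = FALSE, bone = bone, water = water)
  list(
    bone_record = run_simulation(scene_bone, solver),
    water_record = run_simulation(scene_water, solver),
    scene_bone = scene_bone, scene_water = scene_water
  )
}

#' Attenuation of the focal peak
#'
#' Peak focal intensity with bone present expressed as a percent of the peak
#' intensity of the paired water-only simulation:
#' `100 * bone_peak / water_peak`.
#'
#' @param bone_peak,water_peak Peak intensities (Pa^2).
#' @return Percent.
#' @export
compute_attenuation <- function(bone_peak, water_peak) {
  if (any(water_peak <= 0)) {
    stop("degenerate simulation: water peak intensity is zero", call. = FALSE)
  }
  if (any(bone_peak < 0)) stop("negative peak intensity", call. = FALSE)
  100 * bone_peak / water_peak
}

#' Refraction of the focal peak
#'
#' Euclidean distance between the bone and water peak locations, in mm.
#'
#' @param bone_location,water_location Physical coordinates, m.
#' @return Millimeters.
#' @export
compute_refraction <- function(bone_location, water_location) {
  if (length(bone_location) != length(water_location)) {
    stop("locations have different dimensionality", call. = FALSE)
  }
  sqrt(sum((bone_location - water_location)^2)) * 1e3
}

#' Build the surrogate tensors over a parameter grid
#'
#' Sweeps every valid grid point, runs the bone/water pair, and fills the
#' 5-D attenuation (%) and refraction (mm) tensors.  Invalid points (focus
#' inside bone or outside the simulated head) are flagged, never silently
#' zeroed.  A failing simulation marks its entry invalid and the sweep
#' continues; more than 10% failures aborts.  With `checkpoint` set, the
#' partial build is saved after every point and a rerun resumes from it.
#'
#' @param grid A [parameter_grid()].
#' @param solver A [solver_config()].
#' @param grid_spec A [grid_spec()].
#' @param bone,water [material_props()].
#' @param checkpoint Optional path for resumable builds.
#' @param verbose Print per-point progress.
#' @return An object of class `fus_surrogate`: `attenuation`, `refraction`
#'   (5-D arrays), `valid` (logical 5-D array), `grid`, `metadata`.
#' @export
build_surrogate <- function(grid, solver = solver_config(), grid_spec,
                            bone = bone_props(), water = water_props(),
                            checkpoint = NULL, verbose = FALSE) {
  stopifnot(inherits(grid, "fus_grid5"))
  pts <- enumerate_points(grid, grid_spec)
  dims <- unname(vapply(grid$levels, length, 1L))
  done <- array(FALSE, dims)
  attenuation <- array(NA_real_, dims)
  refraction <- array(NA_real_, dims)
  valid <- array(FALSE, dims)
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    prev <- readRDS(checkpoint)
    if (identical(prev$grid$levels, grid$levels)) {
      attenuation <- prev$attenuation
      refraction <- prev$refraction
      valid <- prev$valid
      done <- prev$done
    }
  }

  n_fail <- 0L
  n_valid <- sum(pts$valid)
  t_start <- Sys.time()
  for (r in seq_len(nrow(pts))) {
    sub <- integer(5L)
    for (d in seq_len(5L)) {
      sub[d] <- match(pts[[d]][r], grid$levels[[d]])
    }
    ai <- matrix(sub, 1L)
    if (done[ai]) next
    if (!pts$valid[r]) {
      done[ai] <- TRUE
      next
    }
    point <- point_from_row(pts[r, ])
    t0 <- proc.time()[3L]
    res <- tryCatch(
      {
        pair <- simulate_pair(point, solver, grid_spec, bone, water)
        pb <- extract_peak(pair$bone_record, pair$scene_bone$search_mask)
        pw <- extract_peak(pair$water_record, pair$scene_water$search_mask)
        list(att = compute_attenuation(pb$peak_intensity, pw$peak_intensity),
             ref = compute_refraction(pb$location, pw$location))
      },
      error = function(e) e
    )
    if (inherits(res, "error")) {
      n_fail <- n_fail + 1L
      done[ai] <- TRUE
      if (verbose) message(sprintf("point %d failed: %s", r, conditionMessage(res)))
      if (n_fail > 0.1 * n_valid) {
        stop(sprintf(
          "aborting sweep: %d of %d simulations failed (last: %s)",
          n_fail, n_valid, conditionMessage(res)), call. = FALSE)
      }
    } else {
      attenuation[ai] <- res$att
      refraction[ai] <- res$ref
      valid[ai] <- TRUE
      done[ai] <- TRUE
      if (verbose) {
        message(sprintf("point %d/%d: attenuation %.2f%%, refraction %.2f mm (%.1f s)",
                        r, nrow(pts), res$att, res$ref, proc.time()[3L] - t0))
      }
    }
    if (!is.null(checkpoint)) {
      saveRDS(list(grid = grid, attenuation = attenuation,
                   refraction = refraction, valid = valid, done = done),
              checkpoint)
    }
  }

  structure(
    list(
      attenuation = attenuation, refraction = refraction, valid = valid,
      grid = grid,
      metadata = list(
        solver = unclass(solver), grid_spec = unclass(grid_spec),
        bone = unclass(bone), water = unclass(water),
        n_failed = n_fail,
        built = format(t_start, "%Y-%m-%d %H:%M:%S"),
        version = as.character(utils::packageVersion("fusbone"))
      )
    ),
    class = "fus_surrogate"
  )
}

#' @export
print.fus_surrogate <- function(x, ...) {
  cat(sprintf("<fus_surrogate> %s grid, %d/%d valid entries\n",
              paste(dim(x$attenuation), collapse = " x "),
              sum(x$valid), length(x$valid)))
  if (any(x$valid)) {
    cat(sprintf("  attenuation %% in [%.3g, %.3g], refraction mm in [%.3g, %.3g]\n",
                min(x$attenuation[x$valid]), max(x$attenuation[x$valid]),
                min(x$refraction[x$valid]), max(x$refraction[x$valid])))
  }
  invisible(x)
}

#' Serialize / restore surrogate tensors
#'
#' R's native serialization; arrays round-trip bit-exactly.
#'
#' @param surrogate A `fus_surrogate`.
#' @param path File path.
#' @return `read_surrogate` returns the restored object.
#' @export
write_surrogate <- function(surrogate, path) {
  stopifnot(inherits(surrogate, "fus_surrogate"))
  saveRDS(surrogate, path)
  invisible(path)
}

#' @rdname write_surrogate
#' @export
read_surrogate <- function(path) {
  s <- readRDS(path)
  if (!inherits(s, "fus_surrogate")) {
    stop("not a serialized surrogate", call. = FALSE)
  }
  s
}
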