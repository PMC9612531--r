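# Shared fixtures, all generated in code.  Expensive objects are memoized in
# `.fixture_cache` so several test files can reuse one computation.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Hand-built plane-wave scene: water (optionally uniform absorption or a
# bone slab), line source spanning the full transverse width, periodic
# transverse axis (pml 0) so the wave stays an exact plane wave.
plane_scene <- function(n1 = 256, n2 = 16, dx = 5e-4, f0 = 5e5, alpha = 0,
                        amp = 1e5, slab_planes = NULL, bone = bone_props(),
                        src_plane = 15L) {
  g <- grid_spec(c(n1, n2), dx, pml_size = c(10L, 0L))
  w <- material_props(1000, 1482, 0, 2)
  dens <- array(w$density, g$shape)
  spd <- array(w$sound_speed, g$shape)
  ab <- array(alpha, g$shape)
  if (!is.null(slab_planes)) {
    dens[slab_planes, ] <- bone$density
    spd[slab_planes, ] <- bone$sound_speed
    ab[slab_planes, ] <- absorption_at(bone, f0)
  }
  src <- array(FALSE, g$shape)
  src[src_plane, ] <- TRUE
  tx <- transducer_spec(0.02, 0.02, f0, source_pressure = amp)
  structure(
    list(grid = g, transducer = tx, density_map = dens, speed_map = spd,
         absorption_map = ab, source_mask = src,
         search_mask = array(TRUE, g$shape),
         source_signal = function(t) amp * sin(2 * pi * f0 * t),
         bone_thickness = if (is.null(slab_planes)) 0 else length(slab_planes) * dx,
         has_bone = !is.null(slab_planes), water = w, bone = bone),
    class = "fus_scene")
}

# lossless plane-wave reference run with probes at rows 60/120/170
plane_lossless_record <- function() {
  cached("plane_lossless", {
    sc <- plane_scene()
    sens <- array(FALSE, sc$grid$shape)
    sens[c(60, 120, 170), 8] <- TRUE
    run_simulation(sc, solver_config(cfl = 0.3, t_end = 1.2e-4),
                   sensor_mask = sens)
  })
}

# steady-state amplitude of a sensor channel over the last fifth of a run
steady_amplitude <- function(record, channel = 1L, frac = 0.8) {
  n <- record$n_steps
  win <- round(frac * n):n
  (max(record$sensor_data[win, channel]) -
     min(record$sensor_data[win, channel])) / 2
}

# amplitude within an explicit time gate
gated_amplitude <- function(record, t1, t2, channel = 1L) {
  i <- max(1L, round(t1 / record$dt)):min(record$n_steps, round(t2 / record$dt))
  (max(record$sensor_data[i, channel]) - min(record$sensor_data[i, channel])) / 2
}

# Toy 2-D study space: two levels per axis, every point valid, one
# zero-thickness level so the degenerate-slab property is exercised.
toy_parameter_grid <- function() {
  parameter_grid(
    frequency = c(3.5e5, 5e5),
    thickness = c(0, 2.25e-3),
    trajectory = c(75, 90),
    depth = c(2.25e-2, 3e-2),
    diameter = c(1.5e-2, 1.8e-2)
  )
}

toy_grid_spec <- function() {
  suggest_grid(diameter = 1.8e-2, focal_depth = 3e-2, trajectory_deg = 75,
               thickness = 2.25e-3, spacing = 7.5e-4, ndim = 2L)
}

# the toy surrogate, built twice (for determinism checks); both cached
toy_surrogates <- function() {
  cached("toy_surrogates", {
    pg <- toy_parameter_grid()
    gs <- toy_grid_spec()
    cfg <- solver_config()
    list(first = build_surrogate(pg, cfg, gs),
         second = build_surrogate(pg, cfg, gs))
  })
}

# a synthetic (not simulated) surrogate with random tensors, for
# interpolation tests
synthetic_surrogate <- function(dims = c(3L, 3L, 2L, 3L, 2L), seed = 42L,
                                invalidate = NULL) {
  set.seed(seed)
  levels <- list(
    frequency = sort(runif(dims[1L], 2e5, 1e6)),
    thickness = sort(runif(dims[2L], 0, 0.012)),
    trajectory = sort(runif(dims[3L], 45, 90)),
    depth = sort(runif(dims[4L], 0.01, 0.08)),
    diameter = sort(runif(dims[5L], 0.01, 0.08))
  )
  grid <- structure(list(axes = names(levels), levels = levels),
                    class = "fus_grid5")
  valid <- array(TRUE, dims)
  if (!is.null(invalidate)) valid[invalidate] <- FALSE
  structure(
    list(attenuation = array(runif(prod(dims), 0, 100), dims),
         refraction = array(runif(prod(dims), 0, 20), dims),
         valid = valid, grid = grid,
         metadata = list(synthetic = TRUE)),
    class = "fus_surrogate")
}

# independent 32-corner multilinear oracle (product weights), used to check
# the axis-collapse implementation in the package
brute_force_query <- function(surr, x) {
  axes <- surr$grid$levels
  cell <- integer(5L)
  wts <- numeric(5L)
  for (d in 1:5) {
    lv <- axes[[d]]
    i <- findInterval(x[d], lv, rightmost.closed = TRUE)
    cell[d] <- i
    wts[d] <- (x[d] - lv[i]) / (lv[i + 1L] - lv[i])
  }
  att <- 0
  ref <- 0
  for (corner in 0:31) {
    bits <- as.integer(intToBits(corner))[1:5]
    idx <- cell + bits
    w <- prod(ifelse(bits == 1L, wts, 1 - wts))
    att <- att + w * surr$attenuation[matrix(idx, 1L)]
    ref <- ref + w * surr$refraction[matrix(idx, 1L)]
  }
  list(attenuation = att, refraction = ref)
}
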