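test_that("plane wave propagates at the water sound speed", {
  sc <- plane_scene()
  sens <- array(FALSE, sc$grid$shape)
  probe_rows <- seq(40, 200, by = 10)
  sens[probe_rows, 8] <- TRUE
  rec <- run_simulation(sc, solver_config(cfl = 0.3, t_end = 7e-5),
                        sensor_mask = sens)
  # first-arrival time at each probe: first crossing of 5% of the drive
  arrivals <- apply(rec$sensor_data, 2,
                    function(s) which(abs(s) > 0.05 * 1e5)[1]) * rec$dt
  distance <- (probe_rows - 15) * sc$grid$spacing
  speed <- unname(coef(lm(distance ~ arrivals))[2])
  expect_equal(speed, 1482, tolerance = 0.01)
})

test_that("additive source calibration reaches the drive amplitude", {
  sc <- plane_scene()
  rec <- plane_lossless_record()
  # radiated steady amplitude equals the drive within ~2%
  for (ch in 1:3) {
    expect_equal(steady_amplitude(rec, ch), 1e5, tolerance = 0.02)
  }
  # record invariants: non-negative, source voxels reach the drive amplitude
  expect_true(all(rec$max_pressure >= 0))
  expect_gte(max(rec$max_pressure[sc$source_mask]), 1e5 * (1 - 1e-3))
})

test_that("amplitude follows Beer-Lambert decay in a lossy medium", {
  alpha <- 30   # Np/m
  sc <- plane_scene(alpha = alpha)
  sens <- array(FALSE, sc$grid$shape)
  sens[c(60, 120, 170), 8] <- TRUE
  rec <- run_simulation(sc, solver_config(cfl = 0.3, t_end = 1.2e-4),
                        sensor_mask = sens)
  ref <- plane_lossless_record()
  dx <- sc$grid$spacing
  # normalize by the lossless run so only the absorption factor remains
  for (pair in list(c(1, 2), c(1, 3))) {
    travelled <- (c(60, 120, 170)[pair[2]] - c(60, 120, 170)[pair[1]]) * dx
    measured <- (steady_amplitude(rec, pair[2]) / steady_amplitude(rec, pair[1])) /
      (steady_amplitude(ref, pair[2]) / steady_amplitude(ref, pair[1]))
    expect_equal(measured, exp(-alpha * travelled), tolerance = 0.02)
  }
})

test_that("PML swallows a normally incident wavefront", {
  # drive long enough for the front to cross into the far PML, then compare
  # late-time field beyond the front's reflection against the direct wave
  sc <- plane_scene(n1 = 192)
  sens <- array(FALSE, sc$grid$shape)
  sens[170, 8] <- TRUE
  rec <- run_simulation(sc, solver_config(cfl = 0.3, t_end = 1.4e-4),
                        sensor_mask = sens)
  direct <- steady_amplitude(rec)
  # a reflected wave would beat against the incident one; the steady
  # amplitude ripple across neighbouring voxels bounds the reflection
  sens2 <- array(FALSE, sc$grid$shape)
  sens2[160:170, 8] <- TRUE
  rec2 <- run_simulation(sc, solver_config(cfl = 0.3, t_end = 1.4e-4),
                         sensor_mask = sens2)
  amps <- vapply(seq_len(11), function(ch) steady_amplitude(rec2, ch), 1)
  ripple <- (max(amps) - min(amps)) / (max(amps) + min(amps))
  expect_lt(ripple, 0.01)
  expect_equal(direct, 1e5, tolerance = 0.02)
})

test_that("reciprocity holds for swapped source and receiver", {
  g <- grid_spec(c(96, 96), 5e-4, pml_size = 10)
  w <- material_props(1000, 1482, 0, 2)
  mk <- function(src_idx) {
    src <- array(FALSE, g$shape)
    src[src_idx[1], src_idx[2]] <- TRUE
    tx <- transducer_spec(0.02, 0.02, 5e5, source_pressure = 1e5)
    structure(list(grid = g, transducer = tx,
                   density_map = array(w$density, g$shape),
                   speed_map = array(w$sound_speed, g$shape),
                   absorption_map = array(0, g$shape), source_mask = src,
                   search_mask = array(TRUE, g$shape), water = w,
                   bone = bone_props(), has_bone = FALSE),
              class = "fus_scene")
  }
  a <- c(30L, 40L)
  b <- c(70L, 60L)
  cfg <- solver_config(cfl = 0.3, t_end = 6e-5)
  rec_ab <- run_simulation(mk(a), cfg)
  rec_ba <- run_simulation(mk(b), cfg)
  p_at_b <- rec_ab$max_pressure[b[1], b[2]]
  p_at_a <- rec_ba$max_pressure[a[1], a[2]]
  expect_equal(p_at_b, p_at_a, tolerance = 0.01)
})

test_that("focal peak location is stable under grid refinement", {
  # strongly focused bowl so the focal lobe clearly dominates the near field
  tx <- transducer_spec(0.02, 0.018, 5e5)
  run_at <- function(dx) {
    gs <- suggest_grid(0.02, 0.018, 90, 0, dx, ndim = 2L)
    sc <- assemble_scene(gs, tx, 0, with_bone = FALSE)
    rec <- run_simulation(sc, solver_config())
    # peak position relative to the geometric focus (grids differ in extent)
    extract_peak(rec, sc$search_mask)$location - sc$geometry$center
  }
  coarse <- run_at(7.5e-4)
  fine <- run_at(3.75e-4)
  expect_lte(max(abs(coarse - fine)), 7.5e-4)  # within one coarse voxel
})

test_that("peak extraction matches an exhaustive argmax", {
  g <- grid_spec(c(32, 32, 32), 5e-4, pml_size = 4)
  rec <- structure(list(max_pressure = array(0, g$shape), grid = g,
                        dt = 1e-7, n_steps = 1L), class = "fus_record")
  # single maximal voxel at known coordinates
  rec$max_pressure[20, 11, 7] <- 3
  rec$max_pressure[5, 5, 5] <- 1
  pk <- extract_peak(rec, array(TRUE, g$shape))
  expect_equal(pk$index, c(20L, 11L, 7L))
  expect_equal(pk$peak_intensity, 9)
  expect_equal(pk$location, (c(20, 11, 7) - 0.5) * 5e-4)

  # uniform field: tie broken at the mask's lowest linear index
  rec$max_pressure[] <- 2
  mask <- array(FALSE, g$shape)
  mask[c(500L, 900L, 20000L)] <- TRUE
  pk <- extract_peak(rec, mask)
  expect_equal(pk$index, as.integer(arrayInd(500L, g$shape)))

  # random field equals a brute-force scan over masked voxels
  set.seed(7)
  rec$max_pressure <- array(runif(prod(g$shape)), g$shape)
  mask <- array(runif(prod(g$shape)) < 0.3, g$shape)
  pk <- extract_peak(rec, mask)
  vals <- ifelse(mask, rec$max_pressure, -Inf)
  expect_equal(pk$peak_intensity, max(vals)^2)
  expect_equal(pk$index, as.integer(arrayInd(which.max(vals), g$shape)))
  expect_error(extract_peak(rec, array(FALSE, g$shape)), "empty")
})

test_that("solver configuration rejects unstable settings", {
  expect_error(solver_config(cfl = 0.8), "cfl")
  expect_error(solver_config(cfl = 0), "cfl")
  expect_error(solver_config(t_end = -1), "t_end")
  expect_error(solver_config(ramp_cycles = -1))
})
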