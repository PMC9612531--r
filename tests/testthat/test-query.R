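point_from_vec <- function(x) {
  parameter_point(x[1], x[2], x[3], x[4], x[5])
}

test_that("query at a grid node returns the stored values exactly", {
  surr <- synthetic_surrogate()
  lv <- surr$grid$levels
  for (idx in list(c(1, 1, 1, 1, 1), c(2, 3, 2, 2, 1), c(3, 3, 2, 3, 2))) {
    x <- vapply(1:5, function(d) lv[[d]][idx[d]], 1)
    res <- query_surrogate(surr, point_from_vec(x))
    expect_identical(res$attenuation, surr$attenuation[matrix(idx, 1)])
    expect_identical(res$refraction, surr$refraction[matrix(idx, 1)])
  }
})

test_that("query at an edge midpoint is the mean of the two nodes", {
  surr <- synthetic_surrogate()
  lv <- surr$grid$levels
  x <- vapply(lv, `[`, 1, 1)
  x[4] <- (lv$depth[1] + lv$depth[2]) / 2
  res <- query_surrogate(surr, point_from_vec(x))
  a1 <- surr$attenuation[1, 1, 1, 1, 1]
  a2 <- surr$attenuation[1, 1, 1, 2, 1]
  expect_equal(res$attenuation, (a1 + a2) / 2, tolerance = 1e-14)
})

test_that("query equals the 32-corner product-weight oracle", {
  surr <- synthetic_surrogate()
  lv <- surr$grid$levels
  set.seed(99)
  for (i in 1:25) {
    x <- vapply(lv, function(v) runif(1, min(v), max(v)), 1)
    res <- query_surrogate(surr, point_from_vec(x))
    oracle <- brute_force_query(surr, x)
    expect_equal(res$attenuation, oracle$attenuation, tolerance = 1e-12)
    expect_equal(res$refraction, oracle$refraction, tolerance = 1e-12)
    # bounded by the enclosing corner values
    expect_gte(res$attenuation, min(surr$attenuation) - 1e-12)
    expect_lte(res$attenuation, max(surr$attenuation) + 1e-12)
  }
})

test_that("queries are continuous across cell boundaries", {
  surr <- synthetic_surrogate()
  lv <- surr$grid$levels
  x <- vapply(lv, function(v) mean(v[1:2]), 1)
  eps <- 1e-9
  base <- lv$frequency[2]
  at <- function(f) {
    x[1] <- f
    query_surrogate(surr, point_from_vec(x))$attenuation
  }
  expect_equal(at(base - eps), at(base + eps), tolerance = 1e-5)
})

test_that("nearest stored simulation uses per-axis proximity, ties lower", {
  surr <- synthetic_surrogate()
  lv <- surr$grid$levels
  x <- vapply(lv, `[`, 1, 1)
  res <- query_surrogate(surr, point_from_vec(x))
  expect_equal(res$nearest_index, rep(1L, 5))
  # exact midpoint on one axis resolves to the lower level
  x[4] <- (lv$depth[1] + lv$depth[2]) / 2
  res <- query_surrogate(surr, point_from_vec(x))
  expect_equal(res$nearest_index[4], 1L)
  expect_equal(res$nearest_point$focal_depth, lv$depth[1])
  # machine-readable print
  expect_output(print(res), "attenuation_percent=.*refraction_mm=.*nearest=")
})

test_that("out-of-range and invalid-region queries error", {
  surr <- synthetic_surrogate()
  lv <- surr$grid$levels
  x <- vapply(lv, `[`, 1, 1)
  x[1] <- max(lv$frequency) * 1.05
  expect_error(query_surrogate(surr, point_from_vec(x)), "out of range")
  # invalidate one corner of the first cell: any query inside errors
  surr_inv <- synthetic_surrogate(invalidate = matrix(c(2, 2, 2, 2, 2), 1))
  xin <- vapply(lv, function(v) mean(v[1:2]), 1)
  expect_error(query_surrogate(surr_inv, point_from_vec(xin)),
               "invalid region")
  # queries exactly on the hull faces are accepted (closed bounding box)
  xmax <- vapply(lv, function(v) v[length(v)], 1)
  expect_s3_class(query_surrogate(surr, point_from_vec(xmax)),
                  "fus_query_result")
})

test_that("vis2d slices reproduce the tensors at grid nodes", {
  surr <- synthetic_surrogate()
  lv <- surr$grid$levels
  fixed <- list(frequency = lv$frequency[2], trajectory = lv$trajectory[1],
                diameter = lv$diameter[2])
  out <- vis2d(surr, fixed, upsample = 1L)
  expect_equal(out$axes, c("thickness", "depth"))
  expect_equal(out$attenuation, surr$attenuation[2, , 1, , 2])
  expect_equal(out$refraction, surr$refraction[2, , 1, , 2])
})

test_that("vis2d upsampling preserves nodes and stays within cell bounds", {
  surr <- synthetic_surrogate()
  lv <- surr$grid$levels
  fixed <- list(frequency = lv$frequency[1], trajectory = lv$trajectory[1],
                diameter = lv$diameter[1])
  factor <- 10L
  out <- vis2d(surr, fixed, upsample = factor)
  coarse <- surr$attenuation[1, , 1, , 1]
  n1 <- length(lv$thickness)
  n2 <- length(lv$depth)
  # coarse nodes sit at every `factor`-th fine sample and match exactly
  node_rows <- seq(1, by = factor, length.out = n1)
  node_cols <- seq(1, by = factor, length.out = n2)
  expect_equal(out$attenuation[node_rows, node_cols], coarse,
               tolerance = 1e-12)
  # convex-combination property within each coarse cell
  for (i in seq_len(n1 - 1)) {
    for (j in seq_len(n2 - 1)) {
      block <- out$attenuation[node_rows[i]:node_rows[i + 1],
                               node_cols[j]:node_cols[j + 1]]
      corners <- coarse[i:(i + 1), j:(j + 1)]
      expect_gte(min(block), min(corners) - 1e-12)
      expect_lte(max(block), max(corners) + 1e-12)
    }
  }
})

test_that("vis2d at node-fixed axes commutes with pointwise queries", {
  surr <- synthetic_surrogate()
  lv <- surr$grid$levels
  fixed <- list(frequency = lv$frequency[2], trajectory = lv$trajectory[2],
                diameter = lv$diameter[1])
  out <- vis2d(surr, fixed, upsample = 4L)
  set.seed(3)
  for (k in 1:8) {
    i <- sample(seq_along(out$coords$thickness), 1)
    j <- sample(seq_along(out$coords$depth), 1)
    x <- c(fixed$frequency, out$coords$thickness[i], fixed$trajectory,
           out$coords$depth[j], fixed$diameter)
    res <- query_surrogate(surr, point_from_vec(x))
    expect_equal(out$attenuation[i, j], res$attenuation, tolerance = 1e-12)
    expect_equal(out$refraction[i, j], res$refraction, tolerance = 1e-12)
  }
})

test_that("comparison rendering reports focal regions and peak offsets", {
  g <- grid_spec(c(64, 64), 5e-4, pml_size = 10)
  gauss <- function(c1, c2) {
    xs <- fusbone:::coord_arrays(g)
    exp(-((xs[[1]] - c1)^2 + (xs[[2]] - c2)^2) / (2 * (2e-3)^2))
  }
  mk_rec <- function(field) {
    structure(list(max_pressure = field, grid = g, dt = 1e-7, n_steps = 1L),
              class = "fus_record")
  }
  mask <- array(TRUE, g$shape)
  ra <- mk_rec(1e5 * gauss(0.016, 0.016))
  # identical records: coinciding regions, zero distance
  out_same <- render_comparison(ra, ra, mask)
  expect_identical(out_same$mask_bone, out_same$mask_water)
  expect_equal(out_same$peak_distance_mm, 0)
  # offset blobs: the reported distance equals the constructed offset
  rb <- mk_rec(0.5e5 * gauss(0.016 + 3e-3, 0.016 + 4e-3))
  out <- render_comparison(rb, ra, mask)
  expect_equal(out$peak_distance_mm, 5, tolerance = 0.2)
  # -3 dB mask equals brute-force thresholding at half the masked maximum
  inten <- ra$max_pressure^2
  expect_identical(out$mask_water, (inten >= 0.5 * max(inten[mask])) & mask)
  # mismatched grids error
  g2 <- grid_spec(c(48, 48), 5e-4, pml_size = 10)
  rc <- structure(list(max_pressure = array(1, g2$shape), grid = g2,
                       dt = 1e-7, n_steps = 1L), class = "fus_record")
  expect_error(render_comparison(ra, rc, mask), "different grids")
  # PNG rendering writes a file
  png_path <- withr::local_tempfile(fileext = ".png")
  render_comparison(rb, ra, mask, png_path = png_path)
  expect_true(file.exists(png_path))
})
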