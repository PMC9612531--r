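# Interpolating queries over the surrogate tensors, nearest-simulation
# comparison rendering, and 2-D parameter-space slices.

# Multilinear interpolation by successive axis collapse.  `axes` is a list of
# strictly increasing coordinate vectors, `arr` an array of matching dims,
# `x` one query point.  Returns NA-propagating interpolant.
interp_multilinear <- function(axes, arr, x) {
  nd <- length(axes)
  for (d in seq_len(nd)) {
    lv <- axes[[d]]
    # collapse the FIRST remaining axis each pass
    i <- findInterval(x[d], lv, rightmost.closed = TRUE)
    w <- if (lv[i + 1L] == lv[i]) 0 else (x[d] - lv[i]) / (lv[i + 1L] - lv[i])
    dims <- dim(arr)
    if (is.null(dims)) dims <- length(arr)
    m <- matrix(arr, dims[1L])
    slice <- (1 - w) * m[i, ] + w * m[i + 1L, ]
    arr <- if (length(dims) > 1L) array(slice, dims[-1L]) else slice
  }
  arr
}

# cell (lower corner index per axis) enclosing x, and range check
locate_cell <- function(axes, x) {
  nd <- length(axes)
  cell <- integer(nd)
  for (d in seq_len(nd)) {
    lv <- axes[[d]]
    if (x[d] < lv[1L] || x[d] > lv[length(lv)]) {
      stop(sprintf(
        "out of range: axis '%s' value %g outside [%g, %g] of the studied space",
        names(axes)[d], x[d], lv[1L], lv[length(lv)]), call. = FALSE)
    }
    cell[d] <- findInterval(x[d], lv, rightmost.closed = TRUE)
  }
  cell
}

#' Query the surrogate by multilinear interpolation
#'
#' Interpolates both tensors 5-linearly at the requested parameter point and
#' reports the nearest stored simulation.  Queries outside the studied
#' parameter space error, as do queries whose enclosing cell touches an
#' invalid grid entry (focus inside bone or outside the simulated head).
#'
#' @param surrogate A [build_surrogate()] result.
#' @param point A [parameter_point()].
#' @return An object of class `fus_query_result` with `attenuation` (%),
#'   `refraction` (mm), `nearest_index` (five axis indices, ties toward the
#'   lower index) and `nearest_point`.
#' @export
query_surrogate <- function(surrogate, point) {
  stopifnot(inherits(surrogate, "fus_surrogate"),
            inherits(point, "fus_point"))
  axes <- surrogate$grid$levels
  x <- unname(c(point$frequency, point$bone_thickness, point$trajectory_deg,
                point$focal_depth, point$transducer_diameter))
  cell <- locate_cell(axes, x)
  # all 2^5 corners of the enclosing cell must be valid
  corners <- as.matrix(expand.grid(lapply(cell, function(i) c(i, i + 1L))))
  if (!all(surrogate$valid[corners])) {
    stop(paste("invalid region: the enclosing cell contains parameter",
               "combinations whose focus lies inside bone or outside the",
               "simulated head"), call. = FALSE)
  }
  nearest <- vapply(seq_len(5L), function(d) {
    which.min(abs(axes[[d]] - x[d]))   # first minimum = lower index on ties
  }, 1L)
  structure(
    list(
      attenuation = interp_multilinear(axes, surrogate$attenuation, x),
      refraction = interp_multilinear(axes, surrogate$refraction, x),
      nearest_index = nearest,
      nearest_point = parameter_point(
        axes$frequency[nearest[1L]], axes$thickness[nearest[2L]],
        axes$trajectory[nearest[3L]], axes$depth[nearest[4L]],
        axes$diameter[nearest[5L]])
    ),
    class = "fus_query_result"
  )
}

#' @export
print.fus_query_result <- function(x, ...) {
  cat(sprintf("attenuation_percent=%.6g refraction_mm=%.6g nearest=%s\n",
              x$attenuation, x$refraction,
              paste(x$nearest_index, collapse = " ")))
  invisible(x)
}

#' Compare the focal fields of a bone/water pair
#'
#' Computes both intensity fields (squared maximum pressure), each field's
#' -3 dB focal region (intensity >= 50% of its own maximum over the search
#' mask), the two peak locations and their distance.  Optionally writes a
#' three-panel PNG (full fields, focal regions, overlay); the underlying
#' arrays are always returned so callers can assert on them.
#'
#' @param bone_record,water_record [run_simulation()] records on one grid.
#' @param search_mask Logical array restricting the peak search and
#'   thresholding.
#' @param png_path Optional output PNG path (2-D records only; 3-D records
#'   are rendered as the mid-plane slice through the two peaks).
#' @return List with `intensity_bone`, `intensity_water`, `mask_bone`,
#'   `mask_water` (-3 dB regions), `peak_bone`, `peak_water` (voxel
#'   indices), `peak_distance_mm`.
#' @export
render_comparison <- function(bone_record, water_record, search_mask,
                              png_path = NULL) {
  stopifnot(inherits(bone_record, "fus_record"),
            inherits(water_record, "fus_record"))
  if (!identical(dim(bone_record$max_pressure),
                 dim(water_record$max_pressure))) {
    stop("records are on different grids", call. = FALSE)
  }
  dx <- bone_record$grid$spacing
  out <- list()
  for (nm in c("bone", "water")) {
    rec <- if (nm == "bone") bone_record else water_record
    inten <- rec$max_pressure^2
    pk <- extract_peak(rec, search_mask)
    mask <- inten >= 0.5 * pk$peak_intensity
    mask <- mask & search_mask
    out[[paste0("intensity_", nm)]] <- inten
    out[[paste0("mask_", nm)]] <- mask
    out[[paste0("peak_", nm)]] <- pk$index
  }
  out$peak_distance_mm <- sqrt(sum(((out$peak_bone - out$peak_water) * dx)^2)) * 1e3
  if (!is.null(png_path)) {
    dims <- dim(bone_record$max_pressure)
    slice_of <- function(a) {
      if (length(dims) == 2L) a else a[, , out$peak_water[3L]]
    }
    grDevices::png(png_path, width = 1500, height = 500)
    graphics::par(mfrow = c(1, 3), mar = c(2, 2, 2, 1))
    graphics::image(slice_of(out$intensity_bone), main = "bone intensity",
                    useRaster = TRUE)
    graphics::image(slice_of(out$intensity_water), main = "water intensity",
                    useRaster = TRUE)
    overlay <- slice_of(out$mask_bone) + 2 * slice_of(out$mask_water)
    graphics::image(overlay, main = "-3 dB focal regions (overlay)",
                    useRaster = TRUE)
    grDevices::dev.off()
  }
  out
}

#' 2-D parameter-space slice maps
#'
#' Fixes three of the five axes at given values (interpolating along them)
#' and returns the attenuation and refraction over the remaining two axes,
#' upsampled by linear interpolation for smooth visualization.  Coarse grid
#' nodes are preserved exactly by the upsampling.
#'
#' @param surrogate A [build_surrogate()] result.
#' @param fixed Named list of exactly three axis = value pairs (axis names
#'   among frequency, thickness, trajectory, depth, diameter).
#' @param upsample Integer upsampling factor per free axis (default 10).
#' @param png_path Optional base path; writes `<base>_attenuation.png` /
#'   `<base>_refraction.png` and matching CSVs.
#' @return List with `attenuation`, `refraction` (matrices), `axes` (the two
#'   free axis names) and `coords` (their upsampled coordinates).
#' @export
vis2d <- function(surrogate, fixed, upsample = 10L, png_path = NULL) {
  stopifnot(inherits(surrogate, "fus_surrogate"))
  axes <- surrogate$grid$levels
  if (length(fixed) != 3L || !all(names(fixed) %in% .axis_names)) {
    stop("`fixed` must name exactly three of the five axes", call. = FALSE)
  }
  free <- setdiff(.axis_names, names(fixed))
  upsample <- max(1L, as.integer(upsample))

  # collapse the three fixed axes by linear interpolation
  collapse <- function(arr) {
    for (nm in names(fixed)) {
      d <- match(nm, .axis_names)
      cur_axes <- dim(arr)   # current dims correspond to remaining axes
      remaining <- attr(arr, "remaining")
      if (is.null(remaining)) remaining <- .axis_names
      dpos <- match(nm, remaining)
      lv <- axes[[nm]]
      v <- fixed[[nm]]
      if (v < lv[1L] || v > lv[length(lv)]) {
        stop(sprintf("out of range: axis '%s' value %g outside [%g, %g]",
                     nm, v, lv[1L], lv[length(lv)]), call. = FALSE)
      }
      i <- findInterval(v, lv, rightmost.closed = TRUE)
      w <- (v - lv[i]) / (lv[i + 1L] - lv[i])
      arr <- collapse_axis(arr, dpos, i, w)
      attr(arr, "remaining") <- setdiff(remaining, nm)
    }
    attr(arr, "remaining") <- NULL
    arr
  }
  # validity: a slice entry is usable only if every tensor entry it touches
  # is valid
  vnum <- collapse(surrogate$valid + 0)
  att <- collapse(surrogate$attenuation)
  ref <- collapse(surrogate$refraction)
  usable <- vnum >= 1 - 1e-12
  att[!usable] <- NA_real_
  ref[!usable] <- NA_real_

  lv1 <- axes[[free[1L]]]
  lv2 <- axes[[free[2L]]]
  fine1 <- upsample_coords(lv1, upsample)
  fine2 <- upsample_coords(lv2, upsample)
  up <- function(m) bilinear_upsample(lv1, lv2, m, fine1, fine2)
  out <- list(
    attenuation = up(att), refraction = up(ref),
    axes = free, coords = stats::setNames(list(fine1, fine2), free)
  )
  if (!is.null(png_path)) {
    for (nm in c("attenuation", "refraction")) {
      grDevices::png(sprintf("%s_%s.png", png_path, nm), 700, 600)
      graphics::image(fine1, fine2, out[[nm]], xlab = free[1L],
                      ylab = free[2L], main = nm, useRaster = TRUE)
      grDevices::dev.off()
      utils::write.csv(
        stats::setNames(as.data.frame(out[[nm]]), signif(fine2, 6)),
        sprintf("%s_%s.csv", png_path, nm))
    }
  }
  out
}

# interpolate array `arr` along axis `dpos` between index i and i+1
collapse_axis <- function(arr, dpos, i, w) {
  dims <- dim(arr)
  if (is.null(dims)) dims <- length(arr)
  nd <- length(dims)
  perm <- c(dpos, seq_len(nd)[-dpos])
  a <- aperm(array(arr, dims), perm)
  m <- matrix(a, dims[dpos])
  slice <- (1 - w) * m[i, ] + w * m[i + 1L, ]
  if (nd > 1L) array(slice, dims[-dpos]) else slice
}

upsample_coords <- function(lv, factor) {
  if (factor == 1L) return(lv)
  out <- numeric(0)
  for (i in seq_len(length(lv) - 1L)) {
    seg <- seq(lv[i], lv[i + 1L], length.out = factor + 1L)
    out <- c(out, seg[-(factor + 1L)])
  }
  c(out, lv[length(lv)])
}

bilinear_upsample <- function(lv1, lv2, m, fine1, fine2) {
  out <- matrix(NA_real_, length(fine1), length(fine2))
  for (jj in seq_along(fine2)) {
    j <- findInterval(fine2[jj], lv2, rightmost.closed = TRUE)
    wj <- (fine2[jj] - lv2[j]) / (lv2[j + 1L] - lv2[j])
    col <- (1 - wj) * m[, j] + wj * m[, j + 1L]
    for (ii in seq_along(fine1)) {
      i <- findInterval(fine1[ii], lv1, rightmost.closed = TRUE)
      wi <- (fine1[ii] - lv1[i]) / (lv1[i + 1L] - lv1[i])
      out[ii, jj] <- (1 - wi) * col[i] + wi * col[i + 1L]
    }
  }
  out
}
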