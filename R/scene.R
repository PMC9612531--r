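# Scene construction: voxelized material maps, bowl transducer, flat bone
# slab, search mask.
#
# Conventions: axis 1 is the beam axis at normal incidence; voxel i has its
# center at (i - 0.5) * spacing (1-based indices); tilting happens in the
# (axis 1, axis 2) plane about the aperture rim point that stays on the bone
# face, so the bone slab position never depends on trajectory.

# Broadcast a per-axis vector to a full array along axis `axis`.
broadcast_axis <- function(v, dims, axis) {
  nd <- length(dims)
  if (axis == 1L) return(array(v, dims))
  perm <- seq_len(nd)
  perm[1L] <- axis
  perm[axis] <- 1L
  aperm(array(v, dims[perm]), perm)
}

# Coordinate arrays (voxel centers, meters) for every axis.
coord_arrays <- function(grid) {
  dims <- grid$shape
  lapply(seq_along(dims), function(d) {
    broadcast_axis((seq_len(dims[d]) - 0.5) * grid$spacing, dims, d)
  })
}

# Analytic bowl geometry after tilting: apex point, sphere center (= geometric
# focus), unit beam axis, aperture half-angle.  Tilt rotates the bowl about
# the aperture rim point in the tilt plane that stays on the bone face.
bowl_geometry <- function(grid, transducer, apex_index = NULL,
                          tilt_deg = 90 - transducer$trajectory_deg) {
  dims <- grid$shape
  nd <- length(dims)
  dx <- grid$spacing
  roc <- transducer$radius_of_curvature
  a <- transducer$diameter / 2
  h <- roc - transducer$focal_depth          # cap depth (apex to rim plane)
  if (is.null(apex_index)) {
    apex_index <- c(grid$pml_size[1L] + 1L,
                    round(dims[-1L] / 2))
  }
  apex <- (apex_index - 0.5) * dx
  e0 <- c(1, rep(0, nd - 1L))
  t2 <- c(0, 1, rep(0, nd - 2L))
  pivot <- apex + h * e0 + a * t2            # rim point kept on the bone face
  tau <- tilt_deg * pi / 180
  rot <- function(v) {
    d <- v - pivot
    d12 <- c(d[1L] * cos(tau) - d[2L] * sin(tau),
             d[1L] * sin(tau) + d[2L] * cos(tau))
    out <- d
    out[1L:2L] <- d12
    pivot + out
  }
  apex_t <- rot(apex)
  axis_t <- c(cos(tau), sin(tau), rep(0, nd - 2L))
  center <- apex_t + roc * axis_t            # sphere center = geometric focus
  list(apex = apex_t, center = center, axis = axis_t,
       pivot = pivot, roc = roc, aperture_radius = a, cap_depth = h,
       half_angle = asin(min(1, a / roc)),
       apex_index = apex_index, rim_plane = apex_index[1L] + round(h / dx))
}

# Sampled points on the cap surface (for analytic fit checks).
cap_sample_points <- function(geom, n_polar = 60L, n_azim = 60L) {
  phis <- seq(0, geom$half_angle, length.out = n_polar)
  back <- (geom$apex - geom$center) / geom$roc   # unit vector center -> apex
  nd <- length(geom$apex)
  # orthonormal frame around `back`
  b1 <- if (nd == 3L) {
    v <- c(0, 0, 1)
    if (abs(sum(v * back)) > 0.9) v <- c(0, 1, 0)
    v <- v - sum(v * back) * back
    v / sqrt(sum(v^2))
  } else {
    v <- c(-back[2L], back[1L])
    v / sqrt(sum(v^2))
  }
  pts <- list()
  if (nd == 3L) {
    b2 <- c(back[2L] * b1[3L] - back[3L] * b1[2L],
            back[3L] * b1[1L] - back[1L] * b1[3L],
            back[1L] * b1[2L] - back[2L] * b1[1L])
    psis <- seq(0, 2 * pi, length.out = n_azim + 1L)[-(n_azim + 1L)]
    for (phi in phis) {
      ring <- t(vapply(psis, function(psi) {
        geom$center + geom$roc *
          (cos(phi) * back + sin(phi) * (cos(psi) * b1 + sin(psi) * b2))
      }, numeric(3L)))
      pts[[length(pts) + 1L]] <- ring
    }
  } else {
    for (phi in phis) {
      pts[[length(pts) + 1L]] <- rbind(
        geom$center + geom$roc * (cos(phi) * back + sin(phi) * b1),
        geom$center + geom$roc * (cos(phi) * back - sin(phi) * b1))
    }
  }
  do.call(rbind, pts)
}

#' Voxelize a focused bowl transducer
#'
#' Rasterizes the spherical-cap shell of a bowl transducer: a voxel belongs
#' to the mask when its center lies within half a voxel diagonal of the
#' defining sphere and inside the aperture cone.  The cap opens along the
#' (possibly tilted) beam axis; tilting rotates the defining sphere about the
#' aperture rim point that stays on the bone face, swinging the focus away
#' from the domain faces.
#'
#' @param grid A [grid_spec()].
#' @param transducer A [transducer_spec()].
#' @param apex_index Voxel index (1-based, length = number of axes) of the
#'   untilted apex; defaults to the first interior plane on the beam axis,
#'   centered transversally.
#' @param tilt_deg Tilt angle in degrees (default `90 - trajectory_deg`).
#' @return Logical array of `grid$shape`; the transducer shell.
#' @export
voxelize_bowl <- function(grid, transducer, apex_index = NULL,
                          tilt_deg = 90 - transducer$trajectory_deg) {
  stopifnot(inherits(grid, "fus_grid"), inherits(transducer, "fus_transducer"))
  geom <- bowl_geometry(grid, transducer, apex_index, tilt_deg)
  dims <- grid$shape
  nd <- length(dims)
  dx <- grid$spacing
  xs <- coord_arrays(grid)
  d2 <- (xs[[1L]] - geom$center[1L])^2 + (xs[[2L]] - geom$center[2L])^2
  if (nd == 3L) d2 <- d2 + (xs[[3L]] - geom$center[3L])^2
  dist <- sqrt(d2)
  shell <- abs(dist - geom$roc) <= dx * sqrt(nd) / 2
  back <- (geom$apex - geom$center) / geom$roc
  dotp <- (xs[[1L]] - geom$center[1L]) * back[1L] +
          (xs[[2L]] - geom$center[2L]) * back[2L]
  if (nd == 3L) dotp <- dotp + (xs[[3L]] - geom$center[3L]) * back[3L]
  cone <- dotp >= pmax(dist, .Machine$double.eps) * cos(geom$half_angle)
  mask <- shell & cone
  if (!any(mask)) stop("bowl voxelization produced an empty mask", call. = FALSE)
  idx <- which(mask, arr.ind = TRUE)
  lo <- grid$pml_size + 1L
  hi <- dims - grid$pml_size
  if (any(idx < matrix(lo, nrow(idx), nd, byrow = TRUE)) ||
      any(idx > matrix(hi, nrow(idx), nd, byrow = TRUE))) {
    stop("geometry error: bowl extends into the PML", call. = FALSE)
  }
  mask
}

#' Flat bone slab mask
#'
#' An axis-aligned slab of `round(thickness / spacing)` consecutive voxel
#' planes perpendicular to the beam axis, starting one plane beyond
#' `standoff_plane`.  The slab is flat regardless of transducer tilt so the
#' bone surface is never aliased.
#'
#' @param grid A [grid_spec()].
#' @param thickness Slab thickness, m (>= 0; 0 gives an empty mask).
#' @param standoff_plane Beam-axis voxel index of the plane the slab's outer
#'   face touches (the slab occupies `standoff_plane + 1, ...`).
#' @return Logical array of `grid$shape`.
#' @export
build_bone_slab <- function(grid, thickness, standoff_plane) {
  stopifnot(inherits(grid, "fus_grid"))
  if (thickness < 0) stop("`thickness` must be >= 0", call. = FALSE)
  n_planes <- as.integer(round(thickness / grid$spacing))
  mask <- array(FALSE, grid$shape)
  if (n_planes == 0L) return(mask)
  first <- as.integer(standoff_plane) + 1L
  last <- first + n_planes - 1L
  if (last > grid$shape[1L] - grid$pml_size[1L]) {
    stop("geometry error: bone slab does not fit inside the interior",
         call. = FALSE)
  }
  planes <- rep(FALSE, grid$shape[1L])
  planes[first:last] <- TRUE
  broadcast_axis(planes, grid$shape, 1L)
}

#' Assemble a simulation scene
#'
#' Builds the voxelized scene for one simulation: two-valued material maps
#' (water everywhere, bone on the flat slab when `with_bone`), the bowl
#' source mask, and the peak-search mask (interior voxels strictly beyond the
#' slab's inner face, outside the transducer concavity and outside the PML).
#' The bone slab's outer face touches the aperture rim plane, so the slab
#' meets the transducer face; its position is identical for the paired
#' water-only scene, which guarantees both members of a bone/water pair share
#' the same search mask.
#'
#' @param grid A [grid_spec()].
#' @param transducer A [transducer_spec()].
#' @param thickness Bone slab thickness, m.
#' @param with_bone Logical; `FALSE` yields the water-only member of a pair
#'   (all voxels water, search mask unchanged).
#' @param bone,water [material_props()] for the two media.
#' @return An object of class `fus_scene`.
#' @export
assemble_scene <- function(grid, transducer, thickness, with_bone = TRUE,
                           bone = bone_props(), water = water_props()) {
  stopifnot(inherits(grid, "fus_grid"), inherits(transducer, "fus_transducer"))
  geom <- bowl_geometry(grid, transducer)
  source_mask <- voxelize_bowl(grid, transducer)
  slab <- build_bone_slab(grid, thickness, geom$rim_plane)
  dims <- grid$shape
  nd <- length(dims)
  dx <- grid$spacing
  f0 <- transducer$carrier_frequency

  density_map <- array(water$density, dims)
  speed_map <- array(water$sound_speed, dims)
  absorption_map <- array(absorption_at(water, f0), dims)
  if (with_bone && any(slab)) {
    density_map[slab] <- bone$density
    speed_map[slab] <- bone$sound_speed
    absorption_map[slab] <- absorption_at(bone, f0)
  }

  # search mask: interior, strictly beyond the slab's inner face, outside the
  # transducer's concave region, never on the source shell
  n_planes <- as.integer(round(thickness / dx))
  slab_inner <- geom$rim_plane + n_planes
  lo <- grid$pml_size + 1L
  hi <- dims - grid$pml_size
  xs <- coord_arrays(grid)
  axis1_idx <- broadcast_axis(seq_len(dims[1L]), dims, 1L)
  search <- axis1_idx > slab_inner
  for (d in seq_len(nd)) {
    idx_d <- broadcast_axis(seq_len(dims[d]), dims, d)
    search <- search & idx_d >= lo[d] & idx_d <= hi[d]
  }
  d2 <- (xs[[1L]] - geom$center[1L])^2 + (xs[[2L]] - geom$center[2L])^2
  if (nd == 3L) d2 <- d2 + (xs[[3L]] - geom$center[3L])^2
  concave <- sqrt(d2) < geom$roc - dx / 2
  back <- (geom$apex - geom$center) / geom$roc
  dotp <- (xs[[1L]] - geom$center[1L]) * back[1L] +
          (xs[[2L]] - geom$center[2L]) * back[2L]
  if (nd == 3L) dotp <- dotp + (xs[[3L]] - geom$center[3L]) * back[3L]
  concave <- concave & (dotp > 0)
  search <- search & !concave & !source_mask

  # source-strength normalization: the rasterized shell is thicker than one
  # voxel in places, so scale the per-voxel drive by the ideal shell voxel
  # count (cap area / dx^2, arc length / dx in 2-D) over the actual count
  ideal_count <- if (nd == 3L) {
    2 * pi * geom$roc * geom$cap_depth / dx^2
  } else {
    2 * geom$roc * geom$half_angle / dx
  }
  source_scale <- ideal_count / sum(source_mask)
  # per-voxel phase correction for the rasterization: a shell voxel at radial
  # distance r from the geometric focus is driven earlier/later so that its
  # contribution arrives at the focus in phase with the ideal cap
  src_sub <- which(source_mask, arr.ind = TRUE)
  src_r <- sqrt(rowSums((sweep(src_sub, 2L, 0.5) * dx -
                           matrix(geom$center, nrow(src_sub), nd,
                                  byrow = TRUE))^2))
  k_w <- 2 * pi * f0 / water$sound_speed
  source_phase <- k_w * (src_r - geom$roc)    # aligned with which(source_mask)

  amp <- transducer$source_pressure
  structure(
    list(
      grid = grid, transducer = transducer, source_scale = source_scale,
      source_phase = source_phase,
      density_map = density_map, speed_map = speed_map,
      absorption_map = absorption_map,
      source_mask = source_mask, search_mask = search,
      source_signal = function(t) amp * sin(2 * pi * f0 * t),
      bone_thickness = thickness, has_bone = as.logical(with_bone),
      bone = bone, water = water,
      geometry = geom, slab_planes = n_planes, slab_inner = slab_inner
    ),
    class = "fus_scene"
  )
}

#' @export
print.fus_scene <- function(x, ...) {
  cat(sprintf(
    "<fus_scene> %s voxels, %s, bone %.1f mm (%d planes), trajectory %g deg\n",
    paste(x$grid$shape, collapse = " x "),
    if (x$has_bone) "bone+water" else "water-only",
    x$bone_thickness * 1e3, x$slab_planes, x$transducer$trajectory_deg))
  invisible(x)
}

# Analytic geometry fit check used when enumerating parameter points:
# bowl inside the interior, focus beyond the slab and inside the interior
# with a 2-voxel margin.
check_geometry <- function(grid, transducer, thickness) {
  geom <- tryCatch(bowl_geometry(grid, transducer),
                   error = function(e) NULL)
  if (is.null(geom)) return(list(ok = FALSE, reason = "invalid geometry"))
  dx <- grid$spacing
  lo_phys <- grid$pml_size * dx
  hi_phys <- (grid$shape - grid$pml_size) * dx
  pts <- cap_sample_points(geom)
  for (d in seq_along(grid$shape)) {
    if (min(pts[, d]) < lo_phys[d] || max(pts[, d]) > hi_phys[d]) {
      return(list(ok = FALSE, reason = "transducer does not fit interior"))
    }
  }
  if (transducer$focal_depth <= thickness) {
    return(list(ok = FALSE, reason = "focus inside bone"))
  }
  margin <- 2 * dx
  focus <- geom$center
  slab_inner_phys <- (geom$rim_plane + round(thickness / dx)) * dx
  if (focus[1L] <= slab_inner_phys + margin) {
    return(list(ok = FALSE, reason = "focus inside bone"))
  }
  for (d in seq_along(grid$shape)) {
    if (focus[d] < lo_phys[d] + margin || focus[d] > hi_phys[d] - margin) {
      return(list(ok = FALSE, reason = "focus outside simulated head"))
    }
  }
  list(ok = TRUE, reason = NA_character_)
}

#' Serialize / restore a scene
#'
#' Scenes round-trip voxel-identically through R's native serialization.
#'
#' @param scene A `fus_scene`.
#' @param path File path.
#' @return `read_scene` returns the restored `fus_scene`.
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "fus_scene"))
  saveRDS(scene, path)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  scene <- readRDS(path)
  if (!inherits(scene, "fus_scene")) stop("not a serialized scene", call. = FALSE)
  scene
}
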