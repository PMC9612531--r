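# Closed-form and semi-analytic reference fields used for validation:
# O'Neil focused-bowl on-axis solution, Rayleigh-Sommerfeld surface integral,
# three-medium slab transmission, and the focal-region AUC deviation metric.

#' On-axis pressure profile container
#'
#' @param positions Strictly increasing positions (m) along the beam axis,
#'   measured from the back of the transducer concavity (the apex).
#' @param pressure Non-negative pressure magnitudes (Pa).
#' @return An object of class `fus_axial_profile` (a data frame with columns
#'   `position_m`, `pressure_pa`).
#' @export
axial_profile <- function(positions, pressure) {
  if (length(positions) != length(pressure)) {
    stop("`positions` and `pressure` lengths differ", call. = FALSE)
  }
  if (any(diff(positions) <= 0)) {
    stop("`positions` must be strictly increasing", call. = FALSE)
  }
  if (any(pressure < 0)) stop("`pressure` must be >= 0", call. = FALSE)
  structure(
    data.frame(position_m = positions, pressure_pa = pressure),
    class = c("fus_axial_profile", "data.frame")
  )
}

#' Export an axial profile as CSV
#'
#' @param profile An [axial_profile()].
#' @param path Output file.
#' @export
write_axial_profile <- function(profile, path) {
  stopifnot(inherits(profile, "fus_axial_profile"))
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

#' O'Neil on-axis pressure of a focused bowl
#'
#' Classic closed-form on-axis field of a uniformly vibrating spherical-cap
#' radiator in a homogeneous medium.  With radius of curvature `A`, cap depth
#' `h`, wavenumber `k` and plane-wave drive amplitude `S = rho c u0`,
#' the magnitude at axial distance `z` from the apex is
#' `2 S A / |A - z| * |sin(k (r1 - z) / 2)|` with
#' `r1 = sqrt(z^2 + 2 h (A - z))` (distance to the cap rim), and the finite
#' limit `S k h` at the geometric focus `z = A`.
#'
#' @param transducer A [transducer_spec()].
#' @param medium A [material_props()] (sound speed sets the wavenumber).
#' @param positions Axial positions (m) from the back of the concavity,
#'   in `(0, 4 * focal_depth]`.
#' @return An [axial_profile()].
#' @export
oneil_axial_pressure <- function(transducer, medium, positions) {
  stopifnot(inherits(transducer, "fus_transducer"),
            inherits(medium, "fus_material"))
  if (any(positions <= 0) || any(positions > 4 * transducer$focal_depth)) {
    stop("`positions` must lie in (0, 4 * focal_depth]", call. = FALSE)
  }
  A <- transducer$radius_of_curvature
  a <- transducer$diameter / 2
  h <- A - sqrt(A^2 - a^2)
  k <- 2 * pi * transducer$carrier_frequency / medium$sound_speed
  S <- transducer$source_pressure
  z <- positions
  r1 <- sqrt(z^2 + 2 * h * (A - z))
  denom <- A - z
  p <- ifelse(
    abs(denom) < 1e-9 * A,
    S * k * h,                                   # focal limit
    2 * S * A / abs(denom) * abs(sin(k * (r1 - z) / 2))
  )
  axial_profile(z, p)
}

#' Rayleigh-Sommerfeld field of a focused bowl
#'
#' Numerical surface integral of the spherical cap (uniform normal velocity
#' `u0 = source_pressure / (rho c)`), discretized in polar rings with at
#' least `elements_per_wavelength` elements per wavelength.  Serves as an
#' independent oracle for [oneil_axial_pressure()] and for solver fields.
#'
#' @param transducer A [transducer_spec()].
#' @param medium A [material_props()].
#' @param points Numeric matrix (n x 3) of field points in a frame whose
#'   origin is the cap apex and whose +x axis is the beam axis (a vector is
#'   taken as on-axis distances from the apex).
#' @param elements_per_wavelength Surface discretization density (>= 4;
#'   default 10).
#' @return Complex pressure per point (Pa); take `Mod()` for magnitudes.
#' @export
rayleigh_field <- function(transducer, medium, points,
                           elements_per_wavelength = 10) {
  stopifnot(inherits(transducer, "fus_transducer"),
            inherits(medium, "fus_material"))
  if (elements_per_wavelength < 4) {
    stop("accuracy error: need >= 4 elements per wavelength", call. = FALSE)
  }
  if (is.null(dim(points))) {
    points <- cbind(points, 0, 0)
  }
  A <- transducer$radius_of_curvature
  a <- transducer$diameter / 2
  k <- 2 * pi * transducer$carrier_frequency / medium$sound_speed
  lambda <- 2 * pi / k
  el <- lambda / elements_per_wavelength
  phi_max <- asin(min(1, a / A))
  n_phi <- max(8L, ceiling(A * phi_max / el))
  # cap apex at origin, beam axis +x, sphere center at (A, 0, 0)
  center <- c(A, 0, 0)
  phis <- (seq_len(n_phi) - 0.5) / n_phi * phi_max
  dphi <- phi_max / n_phi
  src <- list()
  wts <- list()
  for (phi in phis) {
    ring_r <- A * sin(phi)
    n_psi <- max(8L, ceiling(2 * pi * ring_r / el))
    psis <- (seq_len(n_psi) - 0.5) / n_psi * 2 * pi
    # direction from sphere center toward the cap (apex side is -x)
    src[[length(src) + 1L]] <- cbind(
      center[1L] - A * cos(phi),
      A * sin(phi) * cos(psis),
      A * sin(phi) * sin(psis)
    )
    wts[[length(wts) + 1L]] <- rep(A^2 * sin(phi) * dphi * (2 * pi / n_psi),
                                   n_psi)
  }
  src <- do.call(rbind, src)
  wts <- unlist(wts)
  S <- transducer$source_pressure       # = rho c u0
  out <- complex(length.out = nrow(points))
  for (i in seq_len(nrow(points))) {
    d <- sqrt((points[i, 1L] - src[, 1L])^2 +
              (points[i, 2L] - src[, 2L])^2 +
              (points[i, 3L] - src[, 3L])^2)
    if (any(d < el / 2)) {
      stop("field point lies on the source surface", call. = FALSE)
    }
    out[i] <- (-1i * k * S / (2 * pi)) * sum(exp(1i * k * d) / d * wts)
  }
  out
}

#' Plane-wave intensity transmission through a flat layer
#'
#' Standard three-medium (water-bone-water) transmission at normal incidence
#' with a complex wavenumber in the layer (absorption evaluated at the
#' carrier frequency).  Solves the two-interface boundary-value problem and
#' returns the transmitted/incident intensity fraction.
#'
#' @param water,bone [material_props()] of the outer and layer media.
#' @param thickness Layer thickness, m (>= 0).
#' @param frequency Carrier frequency, Hz.
#' @return Intensity transmission fraction in \[0, 1\].
#' @export
slab_transmission <- function(water, bone, thickness, frequency) {
  stopifnot(inherits(water, "fus_material"), inherits(bone, "fus_material"))
  if (thickness < 0) stop("`thickness` must be >= 0", call. = FALSE)
  if (thickness == 0) return(1)
  w <- 2 * pi * frequency
  k1 <- w / water$sound_speed
  alpha2 <- absorption_at(bone, frequency)
  k2 <- w / bone$sound_speed + 1i * alpha2
  z1 <- water$density * water$sound_speed
  z2 <- bone$density * w / k2             # complex layer impedance
  L <- thickness
  # unknowns: r (reflected), A, B (layer), t (transmitted)
  # continuity of p and normal velocity at x = 0 and x = L
  M <- rbind(
    c(-1,              1,                  1,                   0),
    c( 1 / z1,         1 / z2,            -1 / z2,              0),
    c( 0,              exp(1i * k2 * L),   exp(-1i * k2 * L),  -exp(1i * k1 * L)),
    c( 0,              exp(1i * k2 * L) / z2, -exp(-1i * k2 * L) / z2,
       -exp(1i * k1 * L) / z1)
  )
  rhs <- c(1, 1 / z1, 0, 0)
  sol <- solve(M, rhs)
  min(1, Mod(sol[4L])^2)
}

#' Focal-region AUC deviation between two axial profiles
#'
#' Restricts each profile to the contiguous region around its global peak
#' where the intensity (pressure squared) is at least 50% of its own maximum
#' (the -3 dB focal region), integrates the pressure by the trapezoid rule,
#' and returns `100 * |AUC_a - AUC_b| / AUC_b`, with `b` the reference
#' (analytic) profile.
#'
#' @param profile_a,profile_b [axial_profile()]s on the same positions
#'   (resample beforehand).
#' @return Percent deviation.
#' @export
focal_auc_deviation <- function(profile_a, profile_b) {
  stopifnot(inherits(profile_a, "fus_axial_profile"),
            inherits(profile_b, "fus_axial_profile"))
  if (nrow(profile_a) != nrow(profile_b) ||
      max(abs(profile_a$position_m - profile_b$position_m)) >
        1e-9 * max(abs(profile_b$position_m))) {
    stop("profiles must share positions; resample first", call. = FALSE)
  }
  auc_focal <- function(pr) {
    x <- pr$position_m
    y <- pr$pressure_pa
    inten <- y^2
    pk <- which.max(inten)
    if (inten[pk] <= 0) stop("empty focal region", call. = FALSE)
    ok <- inten >= 0.5 * inten[pk]
    lo <- pk
    while (lo > 1L && ok[lo - 1L]) lo <- lo - 1L
    hi <- pk
    while (hi < length(ok) && ok[hi + 1L]) hi <- hi + 1L
    if (hi <= lo) stop("empty focal region", call. = FALSE)
    sel <- lo:hi
    sum(diff(x[sel]) * (y[sel][-1L] + y[sel][-length(sel)]) / 2)
  }
  a <- auc_focal(profile_a)
  b <- auc_focal(profile_b)
  100 * abs(a - b) / b
}

#' Resample an axial profile onto new positions
#'
#' Linear interpolation; positions outside the profile's support error.
#'
#' @param profile An [axial_profile()].
#' @param positions Target positions, m.
#' @return An [axial_profile()].
#' @export
resample_profile <- function(profile, positions) {
  stopifnot(inherits(profile, "fus_axial_profile"))
  if (min(positions) < min(profile$position_m) - 1e-12 ||
      max(positions) > max(profile$position_m) + 1e-12) {
    stop("target positions outside the profile support", call. = FALSE)
  }
  y <- stats::approx(profile$position_m, profile$pressure_pa,
                     xout = positions)$y
  axial_profile(positions, y)
}
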