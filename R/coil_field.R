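# Coil field physics: Biot-Savart evaluation of square and circular loop
# pairs, homogeneity optimization and mapping, and dipole distortion sources.

#' Coil pair geometry
#'
#' Describes one pair of identical coaxial coils (one stimulation axis of a
#' Helmholtz-type system). Units: meters for all lengths; the axis is
#' normalized to unit length on construction.
#'
#' @param shape `"square"` or `"circular"`.
#' @param size Side length (square) or radius (circular) in meters.
#' @param separation Distance between the two coil planes in meters.
#' @param turns Number of windings per coil (>= 1).
#' @param axis Symmetry axis of the pair (any nonzero 3-vector; normalized).
#' @param center Midpoint of the pair in setup coordinates (m).
#' @param polarity `"serial"` (fields of the double-wrapped windings add) or
#'   `"anti_serial"` (windings oppose: the coil field is canceled exactly,
#'   the sham/blanking state).
#'
#' @return An object of class `coil_geometry`.
#' @export
coil_geometry <- function(shape = c("square", "circular"),
                          size,
                          separation,
                          turns = 1,
                          axis = c(0, 0, 1),
                          center = c(0, 0, 0),
                          polarity = c("serial", "anti_serial")) {
  shape <- match.arg(shape)
  polarity <- match.arg(polarity)
  if (!is.finite(size) || size <= 0) stop("'size' must be > 0", call. = FALSE)
  if (!is.finite(separation) || separation <= 0) {
    stop("'separation' must be > 0", call. = FALSE)
  }
  turns <- as.integer(turns)
  if (is.na(turns) || turns < 1L) stop("'turns' must be >= 1", call. = FALSE)
  axis <- unit_vec(as_vec3(axis, "axis"))
  structure(
    list(shape = shape, size = size, separation = separation,
         turns = turns, axis = axis, center = as_vec3(center, "center"),
         polarity = polarity),
    class = "coil_geometry"
  )
}

#' @export
print.coil_geometry <- function(x, ...) {
  cat(sprintf("<coil_geometry> %s pair, %s = %g m, d = %g m, n = %d, %s\n",
              x$shape, if (x$shape == "square") "a" else "r",
              x$size, x$separation, x$turns, x$polarity))
  invisible(x)
}

#' Dipole distortion source
#'
#' A localized magnetic distortion. Hard sources carry a fixed moment
#' (magnetized components); soft sources acquire an induced moment
#' proportional to the local applied field (linear soft-iron material),
#' `m = chi_volume * B_applied / mu0`, where `chi_volume` is an effective
#' polarizability volume (susceptibility times material volume, m^3). The
#' induced moment is computed in a single-scattering approximation: the
#' applied field excludes the source's own field.
#'
#' @param position Source location (m).
#' @param moment Fixed dipole moment (A m^2) for a hard source, or `NULL`.
#' @param chi_volume Effective susceptibility volume (m^3, >= 0) for a soft
#'   source, or `NULL`. Exactly one of `moment`/`chi_volume` must be given.
#'
#' @return An object of class `dipole_source`.
#' @export
dipole_source <- function(position, moment = NULL, chi_volume = NULL) {
  position <- as_vec3(position, "position")
  if (is.null(moment) == is.null(chi_volume)) {
    stop("give exactly one of 'moment' (hard) or 'chi_volume' (soft)",
         call. = FALSE)
  }
  if (!is.null(moment)) {
    moment <- as_vec3(moment, "moment")
    kind <- "hard"
  } else {
    if (!is.finite(chi_volume) || chi_volume < 0) {
      stop("'chi_volume' must be >= 0", call. = FALSE)
    }
    kind <- "soft"
  }
  structure(list(position = position, moment = moment,
                 chi_volume = chi_volume, kind = kind),
            class = "dipole_source")
}

#' Midpoint field of a circular Helmholtz pair
#'
#' Closed-form field magnitude at the midpoint between two coaxial circular
#' coils at the Helmholtz spacing `d = r`:
#' `B = (8 / (5 sqrt(5))) * mu0 * n * I / r`.
#'
#' @param r Coil radius (m, > 0).
#' @param n Windings per coil (>= 1).
#' @param I Coil current (A).
#' @return Field magnitude in tesla.
#' @export
circular_helmholtz_midpoint <- function(r, n, I) {
  if (!is.finite(r) || r <= 0) stop("'r' must be > 0", call. = FALSE)
  if (n < 1) stop("'n' must be >= 1", call. = FALSE)
  (8 / (5 * sqrt(5))) * MU0 * n * I / r
}

# Biot-Savart field (tesla) of straight segments carrying current I at a
# single point. starts/ends are n x 3 matrices. Hanson-Hirshman closed form:
# robust, no small-angle issues.
segment_field <- function(starts, ends, point, I) {
  r1 <- -sweep(starts, 2, point)   # point - start
  r2 <- -sweep(ends, 2, point)
  n1 <- row_norms(r1)
  n2 <- row_norms(r2)
  cr <- cbind(r1[, 2] * r2[, 3] - r1[, 3] * r2[, 2],
              r1[, 3] * r2[, 1] - r1[, 1] * r2[, 3],
              r1[, 1] * r2[, 2] - r1[, 2] * r2[, 1])
  dot <- rowSums(r1 * r2)
  denom <- n1 * n2 * (n1 * n2 + dot)
  scale <- (MU0 * I / (4 * pi)) * (n1 + n2) / denom
  colSums(cr * scale)
}

# shortest distance from a point to each segment
segment_distance <- function(starts, ends, point) {
  d <- ends - starts
  w <- -sweep(starts, 2, point)
  tt <- rowSums(w * d) / rowSums(d * d)
  tt <- pmin(pmax(tt, 0), 1)
  proj <- starts + d * tt
  row_norms(-sweep(proj, 2, point))
}

# vertex polyline (closed) of a single loop; circulation is counterclockwise
# seen from the +axis side, so the central field points along +axis for I > 0
loop_vertices <- function(shape, size, center, axis, n_segments) {
  b <- plane_basis(axis)
  if (shape == "square") {
    ang <- c(45, 135, 225, 315, 45) * pi / 180
    rad <- size / sqrt(2)
  } else {
    ang <- seq(0, 2 * pi, length.out = n_segments + 1)
    rad <- size
  }
  outer(cos(ang) * rad, b$u) + outer(sin(ang) * rad, b$v) +
    matrix(center, length(ang), 3, byrow = TRUE)
}

#' Magnetic field of a single current loop
#'
#' Segment-wise Biot-Savart field of a polygonal (square) or discretized
#' circular loop. Evaluation within a guard distance of the conductor
#' (1e-4 of the loop size) is refused as numerically meaningless.
#'
#' @param shape `"square"` or `"circular"`.
#' @param size Side length or radius (m).
#' @param I Current (A); multiplied by `turns`.
#' @param point Evaluation point (m).
#' @param center Loop center (m).
#' @param axis Loop normal (normalized internally).
#' @param turns Number of windings.
#' @param n_segments Segments for circular discretization (default 3600;
#'   square loops always use 4).
#' @return Field vector in microtesla.
#' @export
loop_field <- function(shape = c("square", "circular"), size, I, point,
                       center = c(0, 0, 0), axis = c(0, 0, 1), turns = 1,
                       n_segments = 3600) {
  shape <- match.arg(shape)
  if (size <= 0) stop("'size' must be > 0", call. = FALSE)
  point <- as_vec3(point, "point")
  axis <- unit_vec(as_vec3(axis, "axis"))
  verts <- loop_vertices(shape, size, as_vec3(center, "center"), axis,
                         n_segments)
  ns <- nrow(verts) - 1L
  starts <- verts[seq_len(ns), , drop = FALSE]
  ends <- verts[seq_len(ns) + 1L, , drop = FALSE]
  guard <- 1e-4 * size
  if (any(segment_distance(starts, ends, point) < guard)) {
    stop(sprintf(
      "evaluation point within guard distance (%g m) of a conductor segment",
      guard), call. = FALSE)
  }
  1e6 * segment_field(starts, ends, point, I * turns)
}

# on-axis axial field (tesla) of a single square loop, side a, at distance z
# from the loop plane, current I (single turn); closed form used by the
# spacing optimizer and as an oracle
square_loop_axial <- function(a, I, z) {
  MU0 * I * a^2 / (2 * pi * (z^2 + a^2 / 4) * sqrt(z^2 + a^2 / 2))
}

#' Optimal separation of a square coil pair
#'
#' Finds the separation `d` of two coaxial square coils of side `a` that
#' nulls the second axial derivative of the pair's on-axis field at the
#' midpoint (the square-coil analogue of the Helmholtz condition `d = r`),
#' by root-bracketing a central-difference second derivative of the
#' closed-form axial field. The result scales linearly with `a`; the ratio
#' is `d/a ~ 0.5445`.
#'
#' @param a Side length (m, > 0).
#' @return Optimal separation `d` in meters.
#' @export
optimal_square_separation <- function(a) {
  if (!is.finite(a) || a <= 0) stop("'a' must be > 0", call. = FALSE)
  h <- 1e-3 * a
  # pair field at axial position z for separation d: f(z - d/2) + f(z + d/2);
  # its second derivative at z = 0 equals 2 f''(d/2)
  d2 <- function(d) {
    z <- d / 2
    (square_loop_axial(a, 1, z + h) - 2 * square_loop_axial(a, 1, z) +
       square_loop_axial(a, 1, z - h)) / h^2
  }
  stats::uniroot(d2, interval = c(0.3 * a, 0.8 * a), tol = 1e-13 * a)$root
}

# field (microtesla) of a point dipole with moment m (A m^2) at displacement
# r (m) from the source
dipole_field <- function(moment, r_vec) {
  r <- vec_norm(r_vec)
  if (r < 1e-12) stop("field requested at the dipole position", call. = FALSE)
  rhat <- r_vec / r
  1e6 * (MU0 / (4 * pi)) * (3 * rhat * sum(moment * rhat) - moment) / r^3
}

# coil-only field (microtesla) of the pairs at a point
pairs_field <- function(pairs, currents, point, n_segments) {
  B <- c(0, 0, 0)
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    if (p$polarity == "anti_serial" || currents[i] == 0) next
    for (s in c(-0.5, 0.5)) {
      B <- B + loop_field(p$shape, p$size, currents[i],
                          point, p$center + s * p$separation * p$axis,
                          p$axis, p$turns, n_segments)
    }
  }
  B
}

#' Total field of a coil system with distortion sources
#'
#' Superposition of the Biot-Savart fields of all coil pairs, a uniform
#' ambient field, fixed (hard) dipole sources, and induced (soft) dipole
#' sources. A soft source's induced moment is proportional to the total
#' applied field at its position -- coils, ambient, and hard sources, but
#' not the source's own field (single-scattering approximation). Pairs in
#' the `anti_serial` (sham) state contribute exactly zero coil field by
#' construction.
#'
#' @param pairs List of [coil_geometry()] objects.
#' @param currents Numeric vector, one current (A) per pair.
#' @param point Evaluation point (m).
#' @param sources Optional list of [dipole_source()] objects.
#' @param ambient Uniform ambient field (microtesla).
#' @param n_segments Circular-loop discretization.
#' @return Field vector in microtesla.
#' @export
system_field <- function(pairs, currents, point, sources = list(),
                         ambient = c(0, 0, 0), n_segments = 3600) {
  if (length(currents) != length(pairs)) {
    stop("'currents' must have one entry per pair", call. = FALSE)
  }
  point <- as_vec3(point, "point")
  ambient <- as_vec3(ambient, "ambient")
  applied_at <- function(x) {
    B <- pairs_field(pairs, currents, x, n_segments) + ambient
    for (s in sources) {
      if (s$kind == "hard") B <- B + dipole_field(s$moment, x - s$position)
    }
    B
  }
  B <- applied_at(point)
  for (s in sources) {
    if (s$kind != "soft" || s$chi_volume == 0) next
    # induced moment from the applied field at the source (B in tesla)
    B_src <- applied_at(s$position) * 1e-6
    m <- s$chi_volume * B_src / MU0
    B <- B + dipole_field(m, point - s$position)
  }
  B
}

#' Field homogeneity map over a grid
#'
#' Evaluates [system_field()] on a grid of points and quantifies homogeneity
#' relative to the central field: the maximum relative deviation of the
#' field magnitude and the maximum angular deviation (radians) of the field
#' direction. `homogeneity_metric` is the larger of the two.
#'
#' @param pairs,currents,sources,ambient,n_segments As in [system_field()].
#' @param grid Matrix (n x 3) of evaluation points (m). The point nearest
#'   the grid centroid is used as the reference.
#' @return An object of class `field_map`: list with `positions`, `fields`
#'   (microtesla), `magnitude_deviation`, `direction_deviation` (rad) and
#'   `homogeneity_metric`.
#' @export
map_homogeneity <- function(pairs, currents, grid, sources = list(),
                            ambient = c(0, 0, 0), n_segments = 3600) {
  grid <- as.matrix(grid)
  if (nrow(grid) == 0L || ncol(grid) != 3L) {
    stop("'grid' must be a nonempty n x 3 matrix of positions", call. = FALSE)
  }
  fields <- t(apply(grid, 1, function(p) {
    system_field(pairs, currents, p, sources, ambient, n_segments)
  }))
  centroid <- colMeans(grid)
  i0 <- which.min(row_norms(sweep(grid, 2, centroid)))
  B0 <- fields[i0, ]
  mag0 <- vec_norm(B0)
  if (mag0 == 0) stop("zero field at the reference point", call. = FALSE)
  mags <- row_norms(fields)
  mag_dev <- max(abs(mags - mag0) / mag0)
  cosang <- pmin(1, pmax(-1, (fields %*% B0) / (mags * mag0)))
  dir_dev <- max(acos(cosang))
  structure(
    list(positions = grid, fields = fields, reference_index = i0,
         magnitude_deviation = mag_dev, direction_deviation = dir_dev,
         homogeneity_metric = max(mag_dev, dir_dev)),
    class = "field_map"
  )
}

#' Three-axis square Helmholtz system of the reference setup
#'
#' Convenience constructor for a tri-axial square coil system. Defaults
#' reproduce the reference geometry: side lengths 223 mm (x), 400 mm (y),
#' 162 mm (z), windings (32, 53, 19), each pair at the optimal
#' square-coil spacing from [optimal_square_separation()].
#'
#' @param sides Side lengths (m) of the x-, y-, z-pairs.
#' @param turns Windings per coil for each pair.
#' @param separations Optional explicit separations (m); default optimal.
#' @param center Common center (m).
#' @return List of three [coil_geometry()] objects (x, y, z).
#' @export
reference_coil_system <- function(sides = c(0.223, 0.400, 0.162),
                                  turns = c(32, 53, 19),
                                  separations = NULL,
                                  center = c(0, 0, 0)) {
  if (is.null(separations)) {
    separations <- vapply(sides, optimal_square_separation, numeric(1))
  }
  axes <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  lapply(1:3, function(i) {
    coil_geometry("square", sides[i], separations[i], turns[i],
                  axes[[i]], center)
  })
}
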