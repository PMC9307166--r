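# In-situ calibration of the coil system: affine voltage-to-field forward
# model, sphere-design control voltages, per-component linear regression,
# inversion to control voltages, accuracy metrics, homogeneity scans and a
# distortion-compensation experiment.

#' Ground-truth setup model
#'
#' The forward voltage-to-field response of a coil system at the specimen
#' position: `B = B_const + D U` (+ optional Gaussian measurement noise),
#' where `U` is the triplet of driver control voltages. Hard- and soft-iron
#' distortions of the coil field and the ambient field are absorbed into
#' `D` and `B_const`. An optional `position_hook` makes the model
#' position-dependent for homogeneity scans: a function of an offset (m)
#' returning `list(D = ..., B_const = ...)`.
#'
#' @param D_true 3x3 voltage-to-field matrix, microtesla per volt
#'   (invertible).
#' @param B_const_true Field at zero control voltage, microtesla.
#' @param measurement_noise_std Gaussian noise per axis, microtesla.
#' @param position_hook Optional `function(position)` as described above.
#' @return Object of class `setup_model`.
#' @export
setup_model <- function(D_true, B_const_true = c(0, 0, 0),
                        measurement_noise_std = 0,
                        position_hook = NULL) {
  D_true <- as.matrix(D_true)
  if (!all(dim(D_true) == c(3, 3))) stop("'D_true' must be 3x3", call. = FALSE)
  if (abs(det(D_true)) < 1e-12) stop("'D_true' must be invertible", call. = FALSE)
  if (measurement_noise_std < 0) stop("noise must be >= 0", call. = FALSE)
  if (!is.null(position_hook)) stopifnot(is.function(position_hook))
  structure(list(D_true = D_true,
                 B_const_true = as_vec3(B_const_true, "B_const_true"),
                 measurement_noise_std = measurement_noise_std,
                 position_hook = position_hook),
            class = "setup_model")
}

#' Setup model backed by the coil-field physics
#'
#' Builds a position-dependent [setup_model()] whose response is computed
#' from Biot-Savart fields of actual coil pairs: control voltage `U_j`
#' drives current `I_j = U_j * amps_per_volt[j]` through pair `j`, and the
#' field at `position` is evaluated with [system_field()], including any
#' dipole distortion sources and the ambient field. `D` and `B_const` at a
#' position are obtained from unit-voltage evaluations (the response is
#' exactly linear in `U`).
#'
#' @param pairs List of three [coil_geometry()] objects.
#' @param amps_per_volt Driver transconductance per axis (A/V), default 1.
#' @param sources List of [dipole_source()] objects.
#' @param ambient Ambient field (microtesla).
#' @param measurement_noise_std Gaussian measurement noise (microtesla).
#' @param n_segments Circular-loop discretization.
#' @return Object of class `setup_model` with a position hook installed.
#' @export
setup_from_coils <- function(pairs, amps_per_volt = c(1, 1, 1),
                             sources = list(), ambient = c(0, 0, 0),
                             measurement_noise_std = 0, n_segments = 3600) {
  stopifnot(length(pairs) == 3L)
  hook <- function(position) {
    B0 <- system_field(pairs, c(0, 0, 0), position, sources, ambient,
                       n_segments)
    D <- matrix(0, 3, 3)
    for (j in 1:3) {
      I <- c(0, 0, 0)
      I[j] <- amps_per_volt[j]
      D[, j] <- system_field(pairs, I, position, sources, ambient,
                             n_segments) - B0
    }
    list(D = D, B_const = B0)
  }
  at0 <- hook(c(0, 0, 0))
  setup_model(at0$D, at0$B_const, measurement_noise_std, hook)
}

#' Uniformly distributed directions on a sphere
#'
#' Deterministic Fibonacci-lattice points scaled to a common magnitude;
#' used both as control-voltage designs for calibration and as field-target
#' probes for verification.
#'
#' @param n Number of directions (>= 4).
#' @param magnitude Common vector magnitude.
#' @return Matrix (n x 3), each row of norm `magnitude`.
#' @export
sphere_directions <- function(n, magnitude = 1) {
  n <- as.integer(n)
  if (is.na(n) || n < 4L) stop("'n' must be >= 4", call. = FALSE)
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  theta <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  rho <- sqrt(pmax(0, 1 - z^2))
  magnitude * cbind(rho * cos(theta), rho * sin(theta), z)
}

#' Forward response of a setup model
#'
#' `B = B_const + D U` at the given position offset, plus measurement noise
#' if configured.
#'
#' @param setup A [setup_model()].
#' @param U Control voltage triplet (V), or an n x 3 matrix of triplets.
#' @param position Offset from the calibrated point (m); requires a
#'   position hook for nonzero offsets.
#' @param noise Override the model's noise std (microtesla).
#' @return Field vector (microtesla), or n x 3 matrix for matrix input.
#' @export
forward_response <- function(setup, U, position = c(0, 0, 0), noise = NULL) {
  stopifnot(inherits(setup, "setup_model"))
  position <- as_vec3(position, "position")
  if (!is.null(setup$position_hook)) {
    par <- setup$position_hook(position)
    D <- par$D; B0 <- par$B_const
  } else {
    if (any(position != 0)) {
      stop("setup has no position hook; only position = c(0,0,0) is defined",
           call. = FALSE)
    }
    D <- setup$D_true; B0 <- setup$B_const_true
  }
  sigma <- noise %||% setup$measurement_noise_std
  if (is.matrix(U)) {
    B <- sweep(U %*% t(D), 2, B0, `+`)
    if (sigma > 0) B <- B + matrix(stats::rnorm(length(B), 0, sigma), nrow(B))
    return(B)
  }
  B <- drop(B0 + D %*% as_vec3(U, "U"))
  if (sigma > 0) B <- B + stats::rnorm(3, 0, sigma)
  B
}

#' Fit the affine coil-system calibration
#'
#' Ordinary least squares of each Cartesian field component on the three
#' control voltages with an intercept, giving the voltage-to-field matrix
#' `D` and the constant field `B_const`. Alternatively `B_const` can be
#' fixed to a zero-voltage measurement and only `D` estimated.
#'
#' @param U Matrix (k x 3) of applied control voltage triplets (V),
#'   k >= 4, spanning 3 independent directions.
#' @param B Matrix (k x 3) of measured fields (microtesla).
#' @param B_const Optional fixed constant field; if supplied, the intercept
#'   is not estimated.
#' @return Object of class `coil_calibration`: `D` (microtesla/V),
#'   `B_const` (microtesla), `residual_std` (per component),
#'   `condition_number` of the regression design.
#' @export
fit_calibration <- function(U, B, B_const = NULL) {
  U <- as.matrix(U); B <- as.matrix(B)
  stopifnot(ncol(U) == 3L, ncol(B) == 3L, nrow(U) == nrow(B))
  joint <- is.null(B_const)
  X <- if (joint) cbind(1, U) else U
  Y <- if (joint) B else sweep(B, 2, as_vec3(B_const, "B_const"))
  if (nrow(X) < ncol(X)) stop("need at least 4 voltage triplets", call. = FALSE)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    sv <- svd(scale(U, scale = FALSE), nu = 0)
    worst <- sv$v[, 3]
    stop(sprintf(
      "rank-deficient voltage design: no variation along direction (%.3g, %.3g, %.3g)",
      worst[1], worst[2], worst[3]), call. = FALSE)
  }
  coefs <- qr.coef(qx, Y)
  fitted <- X %*% coefs
  resid <- Y - fitted
  dfres <- max(1L, nrow(X) - ncol(X))
  if (joint) {
    B_const <- coefs[1, ]
    D <- t(coefs[-1, , drop = FALSE])
  } else {
    D <- t(coefs)
  }
  dimnames(D) <- NULL
  B_const <- unname(B_const)
  structure(list(D = D, B_const = as.numeric(B_const),
                 residual_std = sqrt(colSums(resid^2) / dfres),
                 condition_number = kappa(X, exact = TRUE),
                 n = nrow(X), joint_intercept = joint),
            class = "coil_calibration")
}

#' @export
print.coil_calibration <- function(x, ...) {
  cat("<coil_calibration>\n  D (uT/V):\n")
  print(signif(x$D, 6))
  cat("  B_const (uT):", sprintf("%.6g", x$B_const), "\n")
  cat(sprintf("  residual std (uT): %s   design condition: %.3g\n",
              paste(signif(x$residual_std, 3), collapse = " "),
              x$condition_number))
  invisible(x)
}

#' Control voltages for a target field
#'
#' Inverts the fitted calibration: `U = D^-1 (B_target - B_const)`.
#' Refuses ill-conditioned calibrations (condition number of `D` above
#' `max_condition`), since inverting a near-singular gain matrix commands
#' physically meaningless voltages.
#'
#' @param calib A [fit_calibration()] result.
#' @param target Target field vector (microtesla), or n x 3 matrix.
#' @param max_condition Refusal threshold (default 1e6).
#' @return Voltage triplet (V), or n x 3 matrix.
#' @export
control_voltages <- function(calib, target, max_condition = 1e6) {
  kap <- kappa(calib$D, exact = TRUE)
  if (kap > max_condition) {
    stop(sprintf(
      "calibration matrix is ill-conditioned (condition %.3g > %.3g); refusing inversion",
      kap, max_condition), call. = FALSE)
  }
  if (is.matrix(target)) {
    return(t(solve(calib$D, t(sweep(target, 2, calib$B_const)))))
  }
  drop(solve(calib$D, as_vec3(target, "target") - calib$B_const))
}

#' Accuracy metrics of a stimulus set
#'
#' Per-vector magnitude deviation `|B_achieved| - magnitude` and Euclidean
#' distance `|B_achieved - B_target|`, with summary statistics and the mean
#' Euclidean error as a percentage of the target magnitude.
#'
#' @param targets Matrix (n x 3) of target field vectors of common
#'   magnitude (microtesla).
#' @param achieved Matrix (n x 3) of achieved field vectors (microtesla).
#' @return List with `magnitude_deviation`, `euclidean_distance` (vectors),
#'   their means/stds, `magnitude` and `percent_of_magnitude`
#'   (= mean Euclidean / magnitude * 100).
#' @export
accuracy_metrics <- function(targets, achieved) {
  targets <- as.matrix(targets); achieved <- as.matrix(achieved)
  stopifnot(nrow(targets) == nrow(achieved), ncol(targets) == 3L)
  mags <- row_norms(targets)
  magnitude <- mean(mags)
  if (stats::sd(mags) > 1e-9 * magnitude) {
    warning("target magnitudes are not all equal; using their mean")
  }
  mag_dev <- row_norms(achieved) - magnitude
  eucl <- row_norms(achieved - targets)
  list(magnitude_deviation = mag_dev,
       euclidean_distance = eucl,
       mean_magnitude_deviation = mean(mag_dev),
       std_magnitude_deviation = stats::sd(mag_dev),
       mean_euclidean = mean(eucl),
       std_euclidean = stats::sd(eucl),
       magnitude = magnitude,
       percent_of_magnitude = mean(eucl) / magnitude * 100)
}

#' Spatial homogeneity scan of the commanded stimulus
#'
#' Fits the calibration at the center position, then commands a spherical
#' probe stimulus at every position of a square grid and reports the mean
#' Euclidean error as a percentage of the probe magnitude per position.
#' Defaults follow the verification protocol: a 5 x 5 grid at 500
#' micrometer pitch and a 44-vector probe of 50 microtesla.
#'
#' @param setup A [setup_model()] with a position hook.
#' @param grid_n Grid points per side.
#' @param pitch Grid pitch (m).
#' @param probe_n Number of probe vectors.
#' @param probe_magnitude Probe magnitude (microtesla).
#' @param calib Optional pre-fitted [fit_calibration()]; default fits at
#'   the center from a noise-free voltage-sphere design.
#' @param cal_n,cal_voltage Size and magnitude (V) of the calibration
#'   voltage sphere.
#' @param plane Two setup axes spanned by the grid (`"xy"`, `"xz"`, `"yz"`).
#' @return `data.frame` with columns `x`, `y`, `z` (m), `mean_error_pct`,
#'   `max_error_pct`; the fitted calibration in attribute `"calibration"`.
#' @export
homogeneity_scan <- function(setup, grid_n = 5, pitch = 500e-6,
                             probe_n = 44, probe_magnitude = 50,
                             calib = NULL, cal_n = 162, cal_voltage = 2,
                             plane = c("xy", "xz", "yz")) {
  stopifnot(inherits(setup, "setup_model"))
  if (is.null(setup$position_hook)) {
    stop("homogeneity scan requires a setup with a position hook",
         call. = FALSE)
  }
  plane <- match.arg(plane)
  if (is.null(calib)) {
    Ucal <- sphere_directions(cal_n, cal_voltage)
    Bcal <- forward_response(setup, Ucal)
    calib <- fit_calibration(Ucal, Bcal)
  }
  targets <- sphere_directions(probe_n, probe_magnitude)
  Ucmd <- control_voltages(calib, targets)
  offs <- (seq_len(grid_n) - (grid_n + 1) / 2) * pitch
  ax <- switch(plane, xy = c(1, 2), xz = c(1, 3), yz = c(2, 3))
  res <- expand.grid(a = offs, b = offs)
  out <- data.frame(x = 0, y = 0, z = 0, mean_error_pct = NA_real_,
                    max_error_pct = NA_real_)[rep(1, nrow(res)), ]
  for (i in seq_len(nrow(res))) {
    pos <- c(0, 0, 0)
    pos[ax] <- c(res$a[i], res$b[i])
    achieved <- forward_response(setup, Ucmd, position = pos)
    eucl <- row_norms(achieved - targets)
    out[i, c("x", "y", "z")] <- pos
    out$mean_error_pct[i] <- mean(eucl) / probe_magnitude * 100
    out$max_error_pct[i] <- max(eucl) / probe_magnitude * 100
  }
  rownames(out) <- NULL
  attr(out, "calibration") <- calib
  out
}

#' Distortion-compensation experiment
#'
#' Emulates placing a ferromagnetic bar into a previously calibrated
#' setup: evaluates the spherical probe stimulus at the center using the
#' old (pre-distortion) calibration under the distorted setup, then refits
#' the calibration in the presence of the bar and re-evaluates, and
#' finally measures the off-center spatial inhomogeneity of the
#' recalibrated stimulus.
#'
#' @param pairs,amps_per_volt,sources,ambient,n_segments Coil system as in
#'   [setup_from_coils()]; `sources` are the distortion-free sources.
#' @param bar A [dipole_source()] added as the distortion.
#' @param probe_n,probe_magnitude Probe stimulus (default 44 vectors at 50
#'   microtesla).
#' @param cal_n,cal_voltage Calibration voltage-sphere design.
#' @param grid_n,pitch Inhomogeneity grid (default 5 x 5 at 500 um).
#' @return List with `pre` and `post` accuracy metrics at the center,
#'   `baseline` (no-bar) metrics, and `inhomogeneity` data frames
#'   (`homogeneity_scan()` output) for the distorted and undistorted setup.
#' @export
distortion_experiment <- function(pairs, bar, amps_per_volt = c(1, 1, 1),
                                  sources = list(), ambient = c(0, 0, 0),
                                  probe_n = 44, probe_magnitude = 50,
                                  cal_n = 162, cal_voltage = 2,
                                  grid_n = 5, pitch = 500e-6,
                                  n_segments = 3600) {
  stopifnot(inherits(bar, "dipole_source"))
  setup0 <- setup_from_coils(pairs, amps_per_volt, sources, ambient,
                             n_segments = n_segments)
  setup1 <- setup_from_coils(pairs, amps_per_volt, c(sources, list(bar)),
                             ambient, n_segments = n_segments)
  Ucal <- sphere_directions(cal_n, cal_voltage)
  calib0 <- fit_calibration(Ucal, forward_response(setup0, Ucal))
  targets <- sphere_directions(probe_n, probe_magnitude)
  Ucmd0 <- control_voltages(calib0, targets)
  baseline <- accuracy_metrics(targets, forward_response(setup0, Ucmd0))
  pre <- accuracy_metrics(targets, forward_response(setup1, Ucmd0))
  calib1 <- fit_calibration(Ucal, forward_response(setup1, Ucal))
  Ucmd1 <- control_voltages(calib1, targets)
  post <- accuracy_metrics(targets, forward_response(setup1, Ucmd1))
  inhom_dist <- homogeneity_scan(setup1, grid_n, pitch, probe_n,
                                 probe_magnitude, calib = calib1)
  inhom_base <- homogeneity_scan(setup0, grid_n, pitch, probe_n,
                                 probe_magnitude, calib = calib0)
  list(baseline = baseline, pre = pre, post = post,
       inhomogeneity = inhom_dist, inhomogeneity_baseline = inhom_base)
}
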