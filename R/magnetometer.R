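# Forward model of a distorted, noisy, quantized 3-axis AMR magnetometer;
# synthetic rotation trajectories; ellipsoid-fit calibration; residual and
# oversampling noise statistics.

#' Sensor forward model
#'
#' Parameters of the raw-output model
#' `V_raw = V_bias + (1/g_mag) W B_sensor + noise`, with rounding to integer
#' counts and clipping to the signed 16-bit output range. `W` collects
#' soft-iron distortion, per-axis gain differences and cross-axis
#' sensitivity; `V_bias` collects bridge offsets and hard-iron fields.
#'
#' Only the product `g_mag * W^-1` is identifiable from rotation data, so
#' the calibration convention fixes `det(W) = 1`; ground-truth models meant
#' for exact parameter recovery should use a unit-determinant `W`.
#'
#' @param V_bias Offset vector in counts (LSB).
#' @param W 3x3 distortion matrix (dimensionless, invertible,
#'   condition number < 1e6).
#' @param g_mag Gain in nT per LSB (> 0; default 7.85, a typical value for
#'   the modeled sensor class at its most sensitive range).
#' @param noise_std Per-axis Gaussian noise, microtesla (default 0.54, the
#'   noise floor at 64x oversampling).
#' @param full_scale Field clip in microtesla (default 200, the +/- 2 gauss
#'   range).
#' @param output_rate Sample rate in Hz (default 200).
#' @return An object of class `sensor_model`.
#' @export
sensor_model <- function(V_bias = c(0, 0, 0), W = diag(3), g_mag = 7.85,
                         noise_std = 0.54, full_scale = 200,
                         output_rate = 200) {
  V_bias <- as_vec3(V_bias, "V_bias")
  W <- as.matrix(W)
  if (!all(dim(W) == c(3, 3))) stop("'W' must be 3x3", call. = FALSE)
  if (kappa(W, exact = TRUE) >= 1e6) {
    stop("'W' is ill-conditioned (condition number >= 1e6)", call. = FALSE)
  }
  if (!is.finite(g_mag) || g_mag <= 0) stop("'g_mag' must be > 0", call. = FALSE)
  if (!is.finite(noise_std) || noise_std < 0) {
    stop("'noise_std' must be >= 0", call. = FALSE)
  }
  structure(list(V_bias = V_bias, W = W, g_mag = g_mag,
                 noise_std = noise_std, full_scale = full_scale,
                 output_rate = output_rate),
            class = "sensor_model")
}

# one rotation matrix from a unit quaternion
quat_to_rot <- function(q) {
  q <- q / vec_norm4(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

vec_norm4 <- function(q) sqrt(sum(q^2))

axis_angle_rot <- function(axis, angle) {
  axis <- unit_vec(axis)
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Random rotation trajectory in a uniform field
#'
#' Generates a sequence of sensor orientations emulating free rotation of
#' the magnetometer in a spatially uniform field (e.g. the Earth's field
#' during a hand-held calibration rotation). `"uniform"` draws orientations
#' independently and uniformly on the rotation group (random unit
#' quaternions); `"smooth"` performs a random walk with a bounded per-step
#' rotation angle.
#'
#' @param n Number of samples (>= 1). 36000 samples at the default 200 Hz
#'   emulate a 3-minute rotation.
#' @param field_magnitude Uniform field magnitude, microtesla (default 49.0).
#' @param mode `"uniform"` or `"smooth"`.
#' @param seed Integer RNG seed (reproducible).
#' @param field_direction Unit direction of the ambient field in world
#'   coordinates.
#' @param output_rate Hz, for the timestamps.
#' @param max_step Maximum per-step angle (rad) in smooth mode.
#' @return Object of class `rotation_trajectory`: list with `orientations`
#'   (3 x 3 x n array of world-from-sensor rotations), `timestamps`,
#'   `ambient_field` (microtesla 3-vector) and `seed`.
#' @export
random_rotation_trajectory <- function(n, field_magnitude = 49.0,
                                       mode = c("uniform", "smooth"),
                                       seed = 20220722,
                                       field_direction = c(1, 0, 0),
                                       output_rate = 200,
                                       max_step = 0.05) {
  mode <- match.arg(mode)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be >= 1", call. = FALSE)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  R <- array(0, c(3, 3, n))
  if (mode == "uniform") {
    q <- matrix(stats::rnorm(4L * n), n, 4)
    for (k in seq_len(n)) R[, , k] <- quat_to_rot(q[k, ])
  } else {
    cur <- quat_to_rot(stats::rnorm(4))
    for (k in seq_len(n)) {
      step <- axis_angle_rot(stats::rnorm(3),
                             min(abs(stats::rnorm(1, 0, max_step / 2)),
                                 max_step))
      cur <- cur %*% step
      R[, , k] <- cur
    }
  }
  structure(
    list(orientations = R,
         timestamps = (seq_len(n) - 1L) / output_rate,
         ambient_field = field_magnitude *
           unit_vec(as_vec3(field_direction, "field_direction")),
         seed = seed),
    class = "rotation_trajectory"
  )
}

# ambient field expressed in the sensor frame at every sample (n x 3, uT)
sensor_frame_fields <- function(trajectory) {
  n <- dim(trajectory$orientations)[3]
  B <- matrix(0, n, 3)
  for (k in seq_len(n)) {
    B[k, ] <- crossprod(trajectory$orientations[, , k],
                        trajectory$ambient_field)
  }
  B
}

#' Simulate raw sensor readings along a trajectory
#'
#' Applies the forward model of [sensor_model()] to the sensor-frame field
#' at every sample: bias, distortion, gain, per-axis Gaussian noise (noise
#' expressed in microtesla, applied in counts), rounding to integer counts,
#' and clipping. Fields beyond `full_scale` clip and are flagged via the
#' `"clipped"` attribute rather than raising an error.
#'
#' @param model A [sensor_model()].
#' @param trajectory A [random_rotation_trajectory()] (or any object with
#'   the same fields).
#' @param seed Optional RNG seed for the noise (default: derive from the
#'   trajectory seed).
#' @param quantize Round to integer counts and clip to the signed 16-bit
#'   range (default `TRUE`; `FALSE` yields the continuous forward model,
#'   useful for exact-recovery checks).
#' @return Integer matrix (n x 3) of raw counts with attribute `clipped`
#'   (numeric matrix when `quantize = FALSE`).
#' @export
simulate_raw_readings <- function(model, trajectory, seed = NULL,
                                  quantize = TRUE) {
  stopifnot(inherits(model, "sensor_model"))
  B <- sensor_frame_fields(trajectory)
  clip_field <- abs(B) > model$full_scale
  B[clip_field] <- sign(B[clip_field]) * model$full_scale
  g_ut <- model$g_mag * 1e-3   # uT per LSB
  V <- sweep(B %*% t(model$W) / g_ut, 2, model$V_bias, `+`)
  if (model$noise_std > 0) {
    if (is.null(seed)) seed <- (trajectory$seed %||% 0) %% 2147483647L + 1L
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    V <- V + matrix(stats::rnorm(length(V), 0, model$noise_std / g_ut),
                    nrow(V), 3)
  }
  clip_int <- FALSE
  if (quantize) {
    V <- round(V)
    clip_int <- any(abs(V) > 32767)
    V[V > 32767] <- 32767
    V[V < -32768] <- -32768
    storage.mode(V) <- "integer"
  }
  attr(V, "clipped") <- any(clip_field) || clip_int
  V
}

#' Ellipsoid-fit calibration of raw rotation data
#'
#' Fits the general quadric traced by raw counts from rotation in a uniform
#' field by direct algebraic least squares (unit-norm constraint on the
#' 10 quadric parameters, solved by eigendecomposition of the normal
#' matrix), then extracts the calibration: the ellipsoid center gives
#' `V_bias`; the symmetric-positive-definite square root of the quadratic
#' form gives `W_inv` up to scale; `g_mag` is chosen so calibrated radii
#' equal `reference_magnitude`, with `W_inv` normalized to unit
#' determinant.
#'
#' @param raw Integer or numeric matrix (n x 3) of raw counts, n >= 10,
#'   spanning at least 3 non-coplanar directions.
#' @param reference_magnitude Known uniform field magnitude, microtesla.
#' @return Object of class `ellipsoid_calibration`: `W_inv` (3x3,
#'   symmetric PD, det 1), `V_bias` (LSB), `g_mag` (nT/LSB), `fit_rms`
#'   (microtesla, radial quadric residual).
#' @export
fit_ellipsoid <- function(raw, reference_magnitude) {
  raw <- as.matrix(raw)
  storage.mode(raw) <- "double"
  if (nrow(raw) < 10L) stop("need at least 10 triplets", call. = FALSE)
  if (!is.finite(reference_magnitude) || reference_magnitude <= 0) {
    stop("'reference_magnitude' must be > 0", call. = FALSE)
  }
  ctr <- sweep(raw, 2, colMeans(raw))
  sv <- svd(ctr, nu = 0, nv = 0)$d
  if (sv[3] < 1e-8 * sv[1]) {
    stop("degenerate rotation data: triplets are coplanar (rank deficient)",
         call. = FALSE)
  }
  # scale for conditioning of the quadric design
  s <- mean(row_norms(ctr))
  x <- ctr[, 1] / s; y <- ctr[, 2] / s; z <- ctr[, 3] / s
  D <- cbind(x^2, y^2, z^2, 2 * x * y, 2 * x * z, 2 * y * z,
             2 * x, 2 * y, 2 * z, 1)
  ev <- eigen(crossprod(D), symmetric = TRUE)
  beta <- ev$vectors[, 10]
  A <- matrix(c(beta[1], beta[4], beta[5],
                beta[4], beta[2], beta[6],
                beta[5], beta[6], beta[3]), 3, 3)
  if (sum(diag(A)) < 0) { A <- -A; beta <- -beta }
  gvec <- beta[7:9]
  c0 <- beta[10]
  center_s <- -solve(A, gvec)
  rhs <- drop(crossprod(center_s, A %*% center_s)) - c0
  if (rhs <= 0 || any(eigen(A, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    stop(paste("quadric fit is not an ellipsoid (non-positive-definite",
               "form); check that the data cover enough orientations"),
         call. = FALSE)
  }
  M <- A / rhs                      # (v - c)' M (v - c) = 1 in scaled counts
  E <- sqrtm_spd(M, "quadric form") # = (g/R) W_inv in scaled counts
  V_bias <- center_s * s + colMeans(raw)
  E_counts <- E / s
  detE <- det(E_counts)
  W_inv <- E_counts / detE^(1 / 3)
  g_ut <- reference_magnitude * detE^(1 / 3)    # uT per LSB
  # radial residual of the fit, in uT
  q <- rowSums((sweep(raw, 2, V_bias) %*% E_counts)^2)
  fit_rms <- sqrt(mean((sqrt(q) - 1)^2)) * reference_magnitude
  structure(list(W_inv = W_inv, V_bias = V_bias, g_mag = g_ut * 1e3,
                 fit_rms = fit_rms,
                 reference_magnitude = reference_magnitude),
            class = "ellipsoid_calibration")
}

#' @export
print.ellipsoid_calibration <- function(x, ...) {
  cat("<ellipsoid_calibration>\n")
  cat(sprintf("  g_mag: %.6g nT/LSB   fit RMS: %.4g uT\n", x$g_mag, x$fit_rms))
  cat("  V_bias (LSB):", sprintf("%.4g", x$V_bias), "\n")
  invisible(x)
}

#' Apply an ellipsoid calibration to raw counts
#'
#' Inverts the sensor forward model:
#' `B = g_mag * W_inv (V_raw - V_bias)`, returning fields in microtesla.
#'
#' @param calib An [fit_ellipsoid()] result (or compatible list).
#' @param raw Matrix (n x 3) of raw counts.
#' @return Matrix (n x 3) of calibrated field vectors, microtesla.
#' @export
apply_calibration <- function(calib, raw) {
  raw <- as.matrix(raw)
  storage.mode(raw) <- "double"
  g_ut <- calib$g_mag * 1e-3
  sweep(raw, 2, calib$V_bias) %*% t(calib$W_inv) * g_ut
}

#' Residual statistics of calibrated fields
#'
#' Magnitude residuals `|B| - reference` of calibrated field vectors:
#' mean, standard deviation, and the standard deviation as a percentage of
#' the reference magnitude.
#'
#' @param fields Matrix (n x 3) of calibrated fields (microtesla).
#' @param reference_magnitude Reference field magnitude (microtesla).
#' @return List with `mean`, `std` (microtesla) and `percent_of_reference`.
#' @export
residual_statistics <- function(fields, reference_magnitude) {
  fields <- as.matrix(fields)
  if (nrow(fields) == 0L) stop("no field vectors given", call. = FALSE)
  res <- row_norms(fields) - reference_magnitude
  std <- if (nrow(fields) > 1L) stats::sd(res) else 0
  list(mean = mean(res), std = std,
       percent_of_reference = std / reference_magnitude * 100)
}

#' Oversampling noise model
#'
#' White-noise averaging prediction of the sensor noise floor at higher
#' internal oversampling: `base_std * sqrt(64 / k)` for an oversampling
#' factor `k`, where `base_std` is the per-axis noise at the base 64x
#' setting.
#'
#' @param base_std Noise std at 64x oversampling, microtesla.
#' @param k Oversampling factor (>= 64; the modeled sensor offers 64, 128,
#'   256, 512).
#' @return Predicted noise std, microtesla.
#' @export
oversampled_noise_std <- function(base_std, k) {
  if (any(!is.finite(k)) || any(k < 64)) {
    stop("'k' must be >= 64", call. = FALSE)
  }
  base_std * sqrt(64 / k)
}
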