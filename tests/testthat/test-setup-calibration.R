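# affine coil-system calibration and control-voltage inversion

test_that("sphere directions are uniform, deterministic and well separated", {
  s <- sphere_directions(162, 50)
  expect_equal(nrow(s), 162)
  expect_equal(sqrt(rowSums(s^2)), rep(50, 162), tolerance = 1e-12)
  # uniformity: the mean vector nearly cancels
  expect_lt(sqrt(sum(colMeans(s)^2)), 50 * 3 / sqrt(162))
  # n = 4: minimum pairwise angle above 60 degrees
  s4 <- sphere_directions(4)
  ang <- c()
  for (i in 1:3) for (j in (i + 1):4) {
    ang <- c(ang, acos(sum(s4[i, ] * s4[j, ])) * 180 / pi)
  }
  expect_gt(min(ang), 60)
  expect_error(sphere_directions(3), ">= 4")
})

test_that("forward response is affine with B_const at zero voltage", {
  s <- setup_model(diag(c(25, 25, 25)), c(10, 0, -40))
  expect_equal(forward_response(s, c(0, 0, 0)), c(10, 0, -40))
  expect_equal(forward_response(s, c(1, 1, 1)), c(35, 25, -15))
  # linearity of centered responses
  u1 <- c(0.3, -0.2, 0.5); u2 <- c(-1, 0.4, 0.2)
  b0 <- forward_response(s, c(0, 0, 0))
  expect_equal(forward_response(s, u1 + u2) - b0,
               (forward_response(s, u1) - b0) +
                 (forward_response(s, u2) - b0),
               tolerance = 1e-12)
})

test_that("calibration fit exactly recovers any affine ground truth", {
  set.seed(31)
  for (rep in 1:3) {
    D <- matrix(rnorm(9, 0, 8), 3, 3) + diag(c(25, 28, 22))
    Bc <- rnorm(3, 0, 30)
    s <- setup_model(D, Bc)
    U <- sphere_directions(40, 2)
    cal <- fit_calibration(U, forward_response(s, U))
    expect_equal(cal$D, D, tolerance = 1e-9)
    expect_equal(cal$B_const, Bc, tolerance = 1e-9)
  }
  # fixed-intercept variant
  s <- setup_model(diag(c(25, 25, 25)), c(5, -5, 10))
  U <- sphere_directions(40, 2)
  cal <- fit_calibration(U, forward_response(s, U), B_const = c(5, -5, 10))
  expect_equal(cal$D, diag(c(25, 25, 25)), tolerance = 1e-9)
})

test_that("uncoupled setups fit with zero off-diagonal gains", {
  s <- setup_model(diag(c(25, 30, 20)), c(0, 0, 0))
  U <- sphere_directions(44, 2)
  cal <- fit_calibration(U, forward_response(s, U))
  offdiag <- cal$D[row(cal$D) != col(cal$D)]
  expect_lt(max(abs(offdiag)), 1e-10)
})

test_that("rank-deficient voltage designs are refused with the direction named", {
  U <- cbind(seq(-1, 1, length.out = 10), seq(-1, 1, length.out = 10), 0)
  B <- U %*% diag(3)
  expect_error(fit_calibration(U, B), "rank-deficient")
})

test_that("regression is unbiased and tightens with the design size", {
  D <- diag(c(25, 28, 22)); Bc <- c(10, -20, 30)
  s <- setup_model(D, Bc, measurement_noise_std = 0.1)
  set.seed(37)
  # unbiasedness over repeats, against 3 standard errors
  fits <- replicate(200, fit_calibration(sphere_directions(24, 2),
                                         forward_response(s, sphere_directions(24, 2)))$D)
  m <- apply(fits, c(1, 2), mean)
  se <- apply(fits, c(1, 2), sd) / sqrt(200)
  expect_true(all(abs(m - D) < 3 * se + 1e-9))
  # error shrinks roughly like 1/sqrt(n)
  err_n <- function(n, reps = 40) {
    mean(replicate(reps, {
      U <- sphere_directions(n, 2)
      mean(abs(fit_calibration(U, forward_response(s, U))$D - D))
    }))
  }
  r <- err_n(40) / err_n(640)
  expect_gt(r, 4 / 2)     # expected ratio 4 within a factor of two
  expect_lt(r, 4 * 2)
})

test_that("control voltages invert the calibration", {
  s <- setup_model(matrix(c(25, 2, -1, 1, 28, 3, 0, -2, 22), 3, 3),
                   c(12, -33, 40))
  U <- sphere_directions(44, 2)
  cal <- fit_calibration(U, forward_response(s, U))
  expect_equal(control_voltages(cal, cal$B_const), c(0, 0, 0),
               tolerance = 1e-12)
  targets <- sphere_directions(44, 50)
  ach <- forward_response(s, control_voltages(cal, targets))
  expect_lt(max(abs(ach - targets)), 1e-9)
  # hand example: diagonal 25 uT/V gain, zero offset
  cal2 <- fit_calibration(sphere_directions(10, 1),
                          forward_response(setup_model(diag(c(25, 25, 25))),
                                           sphere_directions(10, 1)))
  expect_equal(control_voltages(cal2, c(50, 0, 0)), c(2, 0, 0),
               tolerance = 1e-9)
})

test_that("ill-conditioned calibrations refuse to invert", {
  cal <- structure(list(D = diag(c(25, 25, 1e-7)), B_const = c(0, 0, 0)),
                   class = "coil_calibration")
  expect_error(control_voltages(cal, c(1, 1, 1)), "ill-conditioned")
})

test_that("accuracy metrics do the stated bookkeeping", {
  targets <- sphere_directions(44, 50)
  am0 <- accuracy_metrics(targets, targets)
  expect_equal(max(abs(am0$euclidean_distance)), 0)
  expect_equal(am0$percent_of_magnitude, 0)
  # a pure +1 uT x offset gives max Euclidean distance exactly 1
  am1 <- accuracy_metrics(targets, sweep(targets, 2, c(-1, 0, 0)))
  expect_equal(max(am1$euclidean_distance), 1, tolerance = 1e-12)
  expect_equal(min(am1$euclidean_distance), 1, tolerance = 1e-12)
  # percent bookkeeping is exact
  set.seed(41)
  ach <- targets + matrix(rnorm(length(targets), 0, 0.2), nrow(targets))
  am2 <- accuracy_metrics(targets, ach)
  expect_equal(am2$percent_of_magnitude, mean(am2$euclidean_distance) / 50 * 100)
  # isotropic noise: mean Euclidean matches a Monte-Carlo oracle
  set.seed(43)
  oracle <- mean(sqrt(rowSums(matrix(rnorm(3e5, 0, 0.2), 1e5, 3)^2)))
  expect_equal(am2$mean_euclidean, oracle, tolerance = 0.1)
})

test_that("homogeneity scan of a position-independent setup is error-free", {
  hook <- function(pos) list(D = diag(c(25, 28, 22)), B_const = c(5, -5, 10))
  s <- setup_model(diag(c(25, 28, 22)), c(5, -5, 10), position_hook = hook)
  sc <- homogeneity_scan(s, grid_n = 3, probe_n = 12)
  expect_lt(max(sc$mean_error_pct), 1e-9)
  expect_equal(nrow(sc), 9)
})

test_that("scan error at the fit point never exceeds the worst off-center error", {
  sys <- reference_coil_system()
  st <- setup_from_coils(sys, ambient = c(18, 0, -45.6),
                         sources = list(dipole_source(c(0.04, 0.01, 0.01),
                                                      chi_volume = 4e-5)))
  sc <- homogeneity_scan(st, grid_n = 3, probe_n = 12, cal_n = 24)
  center <- sc$mean_error_pct[sc$x == 0 & sc$y == 0 & sc$z == 0]
  expect_lte(center, max(sc$mean_error_pct))
})

test_that("nearby soft iron degrades off-center accuracy monotonically", {
  sys <- reference_coil_system()
  worst <- vapply(c(0, 2e-5, 6e-5), function(chi) {
    src <- if (chi > 0) list(dipole_source(c(0.03, 0.005, 0),
                                           chi_volume = chi)) else list()
    st <- setup_from_coils(sys, sources = src, ambient = c(18, 0, -45.6))
    max(homogeneity_scan(st, grid_n = 3, probe_n = 12,
                         cal_n = 24)$mean_error_pct)
  }, numeric(1))
  expect_true(all(diff(worst) > 0))
})

test_that("distortion experiment compensates affine distortions exactly", {
  sys <- reference_coil_system()
  amb <- c(18, 0, -45.6)
  # a zero-susceptibility bar changes nothing
  null_bar <- dipole_source(c(0.03, 0.005, 0), chi_volume = 0)
  de0 <- distortion_experiment(sys, null_bar, ambient = amb,
                               probe_n = 12, cal_n = 24, grid_n = 3)
  expect_equal(de0$pre$percent_of_magnitude,
               de0$baseline$percent_of_magnitude, tolerance = 1e-9)
  # a strong soft bar: large error under the old calibration, compensated
  # to the numerical floor at the calibrated point after refitting
  bar <- dipole_source(c(0.03, 0.005, 0), chi_volume = 6e-5)
  de <- distortion_experiment(sys, bar, ambient = amb,
                              probe_n = 12, cal_n = 24, grid_n = 3)
  expect_gt(de$pre$percent_of_magnitude, 1)
  expect_lt(de$post$percent_of_magnitude, 1e-9)
  # off-center inhomogeneity strictly exceeds the undistorted case
  expect_gt(max(de$inhomogeneity$mean_error_pct),
            max(de$inhomogeneity_baseline$mean_error_pct))
})
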