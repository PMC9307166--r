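# shared fixtures built in code

MU0 <- 4e-7 * pi

# a unit-determinant symmetric positive-definite distortion matrix
spd_unit_det <- function(seed = 42) {
  set.seed(seed)
  A <- matrix(rnorm(9, 0, 0.15), 3, 3)
  W <- diag(3) + (A + t(A)) / 2
  W / det(W)^(1 / 3)
}

# angle in degrees between two 3-vectors, ignoring overall sign
axis_angle_deg <- function(a, b) {
  ca <- abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  acos(min(1, ca)) * 180 / pi
}

# small square-pair system used by several coil tests
small_pair <- function(a = 0.223, turns = 32, axis = c(0, 0, 1)) {
  coil_geometry("square", a, optimal_square_separation(a), turns, axis)
}

# a deterministic stimulus visiting transitions in both orderings
two_way_stimulus <- function(segment_duration = 0.05, magnitude = 50) {
  idx <- c(1, 7, 1, 7, 4, 10, 4, 10, 2, 5, 2, 5, 3, 8, 3, 8)
  mag_stimulus_sequence(magnitude = magnitude,
                        segment_duration = segment_duration,
                        vertex_index = idx)
}
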