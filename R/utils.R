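# Internal helpers shared across modules. Conventions: right-handed setup
# coordinates, meters for geometry, microtesla for fields, origin at the
# nominal specimen position.

#' Vacuum permeability (T m / A)
#' @keywords internal
MU0 <- 4e-7 * pi

# validate a length-3 finite numeric vector
as_vec3 <- function(x, name = deparse(substitute(x))) {
  x <- as.numeric(x)
  if (length(x) != 3L || any(!is.finite(x))) {
    stop(sprintf("'%s' must be a finite numeric vector of length 3", name),
         call. = FALSE)
  }
  x
}

vec_norm <- function(x) sqrt(sum(x^2))

unit_vec <- function(x, name = "axis") {
  n <- vec_norm(x)
  if (n < 1e-12) stop(sprintf("'%s' has zero length", name), call. = FALSE)
  x / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# an orthonormal basis (u, v) spanning the plane perpendicular to unit n
plane_basis <- function(n) {
  ref <- if (abs(n[1]) <= abs(n[2]) && abs(n[1]) <= abs(n[3])) {
    c(1, 0, 0)
  } else if (abs(n[2]) <= abs(n[3])) {
    c(0, 1, 0)
  } else {
    c(0, 0, 1)
  }
  u <- unit_vec(cross3(n, ref))
  v <- cross3(n, u)
  list(u = u, v = v)
}

row_norms <- function(m) sqrt(rowSums(m^2))

# symmetric positive-definite matrix square root via eigendecomposition
sqrtm_spd <- function(m, name = "matrix") {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  if (any(e$values <= 0)) {
    stop(sprintf("'%s' is not positive definite (eigenvalues: %s)",
                 name, paste(signif(e$values, 4), collapse = ", ")),
         call. = FALSE)
  }
  e$vectors %*% (sqrt(e$values) * t(e$vectors))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
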