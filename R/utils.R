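# Small geometry helpers shared across modules.

# Extract an n x 3 coordinate matrix from a tibble with x, y, z columns.
coord_matrix <- function(df) {
  stopifnot(all(c("x", "y", "z") %in% names(df)))
  m <- cbind(df$x, df$y, df$z)
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  m
}

# Replace x, y, z columns of a tibble with the rows of a coordinate matrix.
set_coords <- function(df, m) {
  df$x <- m[, 1]
  df$y <- m[, 2]
  df$z <- m[, 3]
  df
}

# All pairwise Euclidean distances between the rows of two coordinate
# matrices (n x m result). Vectorized; used at fixture scales.
cross_distances <- function(a, b) {
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * (a %*% t(b))
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Random rigid motion
#'
#' Draw a uniformly random rotation (via quaternion) and a random
#' translation, returned as a function that maps an n x 3 coordinate matrix
#' (or a tibble with x/y/z columns) to its rigidly moved image. Used by the
#' equivariance checks.
#'
#' @param translation_scale standard deviation (A) of the translation draw.
#' @return A function of one argument applying the rigid motion.
#' @export
random_rigid_motion <- function(translation_scale = 10) {
  q <- random_quaternions(1)[1, ]
  rot <- quaternion_to_matrix(q)
  tr <- rnorm(3, sd = translation_scale)
  function(x) {
    if (is.data.frame(x)) {
      return(set_coords(x, random_rigid_apply(coord_matrix(x), rot, tr)))
    }
    random_rigid_apply(x, rot, tr)
  }
}

random_rigid_apply <- function(m, rot, tr) {
  sweep(m %*% t(rot), 2, -tr)
}

# Uniform random unit quaternions (Shoemake's method), n x 4 (w, x, y, z).
random_quaternions <- function(n) {
  u1 <- runif(n); u2 <- runif(n); u3 <- runif(n)
  cbind(
    sqrt(1 - u1) * sin(2 * pi * u2),
    sqrt(1 - u1) * cos(2 * pi * u2),
    sqrt(u1) * sin(2 * pi * u3),
    sqrt(u1) * cos(2 * pi * u3)
  )[, c(2, 1, 3, 4), drop = FALSE] # (w, x, y, z) ordering
}

quaternion_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# z-y-z Euler angles (phi in [0,2pi), theta in [0,pi], psi in [0,2pi))
# from unit quaternions; n x 4 in, n x 3 out. Used by the rotational
# entropy histogram.
quaternion_to_euler_zyz <- function(q) {
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  # rotation matrix elements needed for zyz extraction
  r33 <- 1 - 2 * (x^2 + y^2)
  r13 <- 2 * (x * z + w * y)
  r23 <- 2 * (y * z - w * x)
  r31 <- 2 * (x * z - w * y)
  r32 <- 2 * (y * z + w * x)
  theta <- acos(pmin(1, pmax(-1, r33)))
  phi <- atan2(r23, r13)
  psi <- atan2(r32, -r31)
  phi <- ifelse(phi < 0, phi + 2 * pi, phi)
  psi <- ifelse(psi < 0, psi + 2 * pi, psi)
  cbind(phi, theta, psi)
}

# Guarded unit vectors for a matrix of displacement rows; zero rows stay zero.
safe_unit_rows <- function(u, d, eps = 1e-9) {
  scale <- ifelse(d > eps, 1 / d, 0)
  u * scale
}

`%||%` <- function(a, b) if (is.null(a)) b else a
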