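#' Quaternion utilities
#'
#' Orientations throughout the simulator are unit quaternions stored as
#' numeric vectors `c(w, x, y, z)` (scalar-first, Hamilton convention).
#' Pose composition uses right-multiplication, i.e. rotations compose in
#' the local frame of the moving interpreter.
#'
#' @param w,x,y,z quaternion components.
#' @return A numeric vector of length 4 with class `"quat"`.
#' @examples
#' q <- quat_axis_angle(c(0, 0, 1), 180)
#' quat_angle(quat_mul(q, q), quat_identity())  # back to identity
#' @export
quat <- function(w, x, y, z) {
  structure(c(w, x, y, z), class = "quat")
}

#' @rdname quat
#' @export
quat_identity <- function() quat(1, 0, 0, 0)

#' @rdname quat
#' @param q,a,b quaternions.
#' @export
quat_norm <- function(q) sqrt(sum(unclass(q)^2))

#' @rdname quat
#' @param tol tolerance on the unit-norm check.
#' @export
quat_is_unit <- function(q, tol = 1e-9) abs(quat_norm(q) - 1) <= tol

#' @rdname quat
#' @export
quat_normalize <- function(q) {
  n <- quat_norm(q)
  if (n == 0) stop("cannot normalize a zero quaternion")
  structure(unclass(q) / n, class = "quat")
}

#' Hamilton product of two quaternions
#' @rdname quat
#' @export
quat_mul <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  quat(
    a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1]
  )
}

#' @rdname quat
#' @export
quat_conj <- function(q) {
  q <- unclass(q)
  quat(q[1], -q[2], -q[3], -q[4])
}

#' Rotate a 3-vector by a unit quaternion
#' @rdname quat
#' @param v numeric 3-vector.
#' @export
quat_rotate <- function(q, v) {
  q <- unclass(q)
  # q v q* expanded; cheaper than building the rotation matrix
  t2 <- 2 * c(
    q[3] * v[3] - q[4] * v[2],
    q[4] * v[1] - q[2] * v[3],
    q[2] * v[2] - q[3] * v[1]
  )
  v + q[1] * t2 + c(
    q[3] * t2[3] - q[4] * t2[2],
    q[4] * t2[1] - q[2] * t2[3],
    q[2] * t2[2] - q[3] * t2[1]
  )
}

#' Build a quaternion from an axis and an angle in degrees
#' @rdname quat
#' @param axis numeric 3-vector (need not be normalized).
#' @param angle_deg rotation angle in degrees.
#' @export
quat_axis_angle <- function(axis, angle_deg) {
  n <- sqrt(sum(axis^2))
  if (n == 0) {
    if (angle_deg %% 360 != 0) stop("zero axis with non-zero angle")
    return(quat_identity())
  }
  half <- angle_deg * pi / 360
  quat_normalize(quat(cos(half), sin(half) * axis[1] / n,
                      sin(half) * axis[2] / n, sin(half) * axis[3] / n))
}

#' Angular distance between two orientations, in degrees
#'
#' The angle of the relative rotation `a^-1 b`, in `[0, 180]`; insensitive
#' to the quaternion double cover (q and -q are the same rotation).
#' @rdname quat
#' @export
quat_angle <- function(a, b = quat_identity()) {
  d <- abs(sum(unclass(a) * unclass(b)))
  d <- min(d / (quat_norm(a) * quat_norm(b)), 1)
  2 * acos(d) * 180 / pi
}

#' Convert a quaternion to a 3x3 rotation matrix
#' @rdname quat
#' @export
quat_to_matrix <- function(q) {
  q <- unclass(quat_normalize(q))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Draw uniformly distributed random rotations
#'
#' Uses the subgroup algorithm (Shoemake) for the uniform (Haar) measure
#' on SO(3). Returns an `n x 4` matrix of unit quaternions (w, x, y, z).
#' @param n number of rotations.
#' @export
quat_random <- function(n) {
  u1 <- stats::runif(n); u2 <- stats::runif(n); u3 <- stats::runif(n)
  cbind(
    sqrt(u1) * cos(2 * pi * u3),
    sqrt(1 - u1) * sin(2 * pi * u2),
    sqrt(1 - u1) * cos(2 * pi * u2),
    sqrt(u1) * sin(2 * pi * u3)
  )
}

# Row-wise Hamilton product of two n x 4 quaternion matrices.
quat_mul_rows <- function(a, b) {
  cbind(
    a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4],
    a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3],
    a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2],
    a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1]
  )
}

# Small random rotations: angle ~ |N(0, sigma)| about a uniform axis.
quat_random_small <- function(n, sigma) {
  ang <- stats::rnorm(n, 0, sigma)
  ax <- matrix(stats::rnorm(3 * n), ncol = 3)
  nrm <- sqrt(rowSums(ax^2))
  nrm[nrm == 0] <- 1
  ax <- ax / nrm
  cbind(cos(ang / 2), sin(ang / 2) * ax)
}
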