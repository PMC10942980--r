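# Vectorized unit-quaternion algebra. Quaternions are n x 4 matrices with
# columns (w, x, y, z), scalar part first, representing sensor-to-global
# rotations. q and -q encode the same orientation.

#' Normalize quaternions to unit length
#'
#' @param q numeric vector of length 4 or an n x 4 matrix (w, x, y, z).
#' @return Matrix of the same shape with each row scaled to unit norm.
#' @export
quat_normalize <- function(q) {
  q <- quat_as_matrix(q)
  nrm <- sqrt(rowSums(q^2))
  if (any(nrm < 1e-12)) stop("zero quaternion cannot be normalized")
  q / nrm
}

quat_as_matrix <- function(q) {
  if (is.null(dim(q))) {
    if (length(q) %% 4L != 0L) {
      stop("quaternions must have 4 components (w, x, y, z)")
    }
    q <- matrix(q, ncol = 4, byrow = TRUE)
  }
  if (ncol(q) != 4L) stop("quaternions must have 4 components (w, x, y, z)")
  q
}

#' Quaternion (Hamilton) product, row-wise
#'
#' @param a,b n x 4 matrices (or length-4 vectors, recycled by row).
#' @return n x 4 matrix with rows `a[i] * b[i]`.
#' @export
quat_multiply <- function(a, b) {
  a <- quat_as_matrix(a); b <- quat_as_matrix(b)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1L && n > 1L) a <- a[rep(1L, n), , drop = FALSE]
  if (nrow(b) == 1L && n > 1L) b <- b[rep(1L, n), , drop = FALSE]
  cbind(
    a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4],
    a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3],
    a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2],
    a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1]
  )
}

#' Quaternion conjugate (inverse for unit quaternions)
#' @param q n x 4 matrix or length-4 vector.
#' @return Same shape, (w, -x, -y, -z).
#' @export
quat_conjugate <- function(q) {
  q <- quat_as_matrix(q)
  cbind(q[, 1], -q[, 2], -q[, 3], -q[, 4])
}

#' Rotate vectors by quaternions, row-wise
#'
#' @param q n x 4 unit quaternions (or one, recycled).
#' @param v n x 3 matrix of vectors (or one, recycled).
#' @return n x 3 matrix of rotated vectors `R(q[i]) v[i]`.
#' @export
quat_rotate <- function(q, v) {
  q <- quat_as_matrix(q)
  if (is.null(dim(v))) v <- matrix(v, ncol = 3)
  n <- max(nrow(q), nrow(v))
  if (nrow(q) == 1L && n > 1L) q <- q[rep(1L, n), , drop = FALSE]
  if (nrow(v) == 1L && n > 1L) v <- v[rep(1L, n), , drop = FALSE]
  w <- q[, 1]; u <- q[, 2:4, drop = FALSE]
  # R v = v + 2 w (u x v) + 2 u x (u x v)
  uxv <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
               u[, 3] * v[, 1] - u[, 1] * v[, 3],
               u[, 1] * v[, 2] - u[, 2] * v[, 1])
  t2 <- uxv * 2
  v + w * t2 + cbind(u[, 2] * t2[, 3] - u[, 3] * t2[, 2],
                     u[, 3] * t2[, 1] - u[, 1] * t2[, 3],
                     u[, 1] * t2[, 2] - u[, 2] * t2[, 1])
}

#' Convert one unit quaternion to a 3 x 3 rotation matrix
#'
#' @param q length-4 numeric (w, x, y, z); normalized internally.
#' @return Proper orthogonal 3 x 3 matrix.
#' @export
quat_to_matrix <- function(q) {
  q <- quat_normalize(q)
  w <- q[1, 1]; x <- q[1, 2]; y <- q[1, 3]; z <- q[1, 4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Quaternions from a common axis and per-row angles
#'
#' @param axis length-3 axis (normalized internally) or n x 3 matrix.
#' @param angle rotation angles in radians.
#' @return n x 4 matrix of unit quaternions.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  if (is.null(dim(axis))) axis <- matrix(axis, ncol = 3)
  nrm <- sqrt(rowSums(axis^2))
  axis <- axis / ifelse(nrm > 0, nrm, 1)
  n <- max(nrow(axis), length(angle))
  if (nrow(axis) == 1L && n > 1L) axis <- axis[rep(1L, n), , drop = FALSE]
  half <- angle / 2
  cbind(cos(half), axis * sin(half))
}

# Small-rotation quaternion from per-axis angle components (radians): the
# exponential map of the rotation vector, exact for any magnitude.
quat_from_rotvec <- function(rv) {
  if (is.null(dim(rv))) rv <- matrix(rv, ncol = 3)
  ang <- sqrt(rowSums(rv^2))
  axis <- rv / ifelse(ang > 1e-300, ang, 1)
  quat_from_axis_angle(axis, ang)
}

#' Enforce sign continuity of a quaternion time series
#'
#' Flips rows so that consecutive quaternions have non-negative dot product,
#' removing the arbitrary q vs -q sign switches that break averaging and
#' interpolation.
#'
#' @param q n x 4 matrix.
#' @return n x 4 matrix, same orientations, continuous signs.
#' @export
quat_continuous <- function(q) {
  q <- quat_as_matrix(q)
  if (nrow(q) < 2L) return(q)
  d <- rowSums(q[-1, , drop = FALSE] * q[-nrow(q), , drop = FALSE])
  flip <- cumprod(ifelse(d < 0, -1, 1))
  q[-1, ] <- q[-1, , drop = FALSE] * flip
  q
}

#' Mean orientation of a quaternion set
#'
#' Barycenter via the principal eigenvector of the outer-product sum, which is
#' invariant to per-row sign flips.
#'
#' @param q n x 4 matrix of unit quaternions.
#' @return Length-4 unit quaternion (as a 1 x 4 matrix).
#' @export
quat_mean <- function(q) {
  q <- quat_as_matrix(q)
  M <- crossprod(q)
  v <- eigen(M, symmetric = TRUE)$vectors[, 1]
  if (v[1] < 0) v <- -v
  quat_normalize(v)
}
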