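#' Quaternion algebra (Hamilton convention, scalar first)
#'
#' Quaternions are plain numeric vectors `c(w, x, y, z)` in the Hamilton
#' convention with the scalar component first; rotations are active.  A
#' quaternion and its negation encode the same rotation (double cover), so
#' [quat_canonical()] fixes the hemisphere `w >= 0` before any statistics
#' are taken.  Vectorised variants operate on n x 4 row matrices.
#'
#' @param w,x,y,z real components.
#' @return `quat()` returns a numeric vector of length 4.
#' @examples
#' q <- quat(sqrt(2) / 2, sqrt(2) / 2, 0, 0)  # 90 degrees about x
#' quat_to_matrix(q)
#' @export
quat <- function(w, x, y, z) {
  q <- c(w, x, y, z)
  if (!all(is.finite(q))) stop("quaternion components must be finite")
  q
}

#' @rdname quat
#' @export
quat_identity <- function() c(1, 0, 0, 0)

check_quat <- function(q, unit = TRUE, tol = 1e-6) {
  if (!is.numeric(q) || length(q) != 4L)
    stop("a quaternion must be a numeric vector of length 4")
  if (!all(is.finite(q))) stop("quaternion components must be finite")
  if (unit && abs(sqrt(sum(q^2)) - 1) > tol)
    stop("quaternion is not unit norm (|q| = ", format(sqrt(sum(q^2))), ")")
  invisible(q)
}

#' Normalize a quaternion to unit norm
#'
#' @param q numeric length-4 quaternion.
#' @return unit quaternion.
#' @export
quat_normalize <- function(q) {
  check_quat(q, unit = FALSE)
  n <- sqrt(sum(q^2))
  if (n < 1e-12) stop("cannot normalize a (near) zero quaternion")
  q / n
}

#' Canonicalize the quaternion hemisphere
#'
#' Flips the sign so that `w >= 0`; if `w == 0`, the first nonzero of
#' (x, y, z) is made nonnegative.  `q` and `-q` encode the same rotation,
#' and Gaussian modelling of quaternion samples is only meaningful on one
#' hemisphere of the double cover.
#'
#' @param q quaternion.
#' @return sign-canonical quaternion.
#' @export
quat_canonical <- function(q) {
  check_quat(q, unit = FALSE)
  i <- which(abs(q) > 0)
  if (length(i) && q[i[1L]] < 0) -q else q
}

#' Hamilton product of two quaternions
#'
#' @param a,b unit quaternions `c(w, x, y, z)`.
#' @return the product `a` %*% `b` (rotation `b` followed by `a` for active
#'   rotations composed on the left).
#' @export
qmul <- function(a, b) {
  check_quat(a, unit = FALSE); check_quat(b, unit = FALSE)
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Inverse (conjugate) of a unit quaternion
#'
#' @param q unit quaternion.
#' @return `c(w, -x, -y, -z)` such that `qmul(q, qinv(q))` is the identity.
#' @export
qinv <- function(q) {
  check_quat(q, unit = FALSE)
  n2 <- sum(q^2)
  if (n2 < 1e-24) stop("cannot invert a zero quaternion")
  c(q[1], -q[2], -q[3], -q[4]) / n2
}

#' Rotation matrix of a unit quaternion
#'
#' @param q unit quaternion (norm within 1e-6 of 1).
#' @return 3 x 3 rotation matrix (orthonormal, det +1).  `q` and `-q` map
#'   to the same matrix.
#' @export
quat_to_matrix <- function(q) {
  check_quat(q, unit = TRUE)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Unit quaternion of a rotation matrix
#'
#' Shepperd's branch method; the result is hemisphere-canonical.
#'
#' @param R 3 x 3 rotation matrix.
#' @return unit quaternion with `w >= 0`.
#' @export
matrix_to_quat <- function(R) {
  if (!is.matrix(R) || any(dim(R) != 3L)) stop("R must be a 3 x 3 matrix")
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s, (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
           (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
           0.25 * s, (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  quat_canonical(quat_normalize(q))
}

#' Rotate a 3-vector by a unit quaternion
#'
#' Computes the pure-quaternion sandwich `Im{q (0, v) q^-1}`.
#'
#' @param q unit quaternion.
#' @param v numeric 3-vector.
#' @return rotated 3-vector, same norm as `v`.
#' @export
rotate_vector <- function(q, v) {
  check_quat(q, unit = TRUE)
  if (!is.numeric(v) || length(v) != 3L || !all(is.finite(v)))
    stop("v must be a finite numeric 3-vector")
  qmul(qmul(q, c(0, v)), qinv(q))[2:4]
}

#' Quaternion of an axis-angle rotation
#'
#' @param axis 3-vector rotation axis (normalized internally).
#' @param angle rotation angle in radians.
#' @return unit quaternion.
#' @export
axis_angle_quat <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("rotation axis must be nonzero")
  c(cos(angle / 2), sin(angle / 2) * axis / n)
}

#' Quaternion of a rotation-vector (axis times angle)
#'
#' The zero vector maps to the identity quaternion.
#'
#' @param w numeric 3-vector, direction = axis, norm = angle (rad).
#' @return unit quaternion.
#' @export
rotvec_quat <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(quat_identity())
  c(cos(th / 2), sin(th / 2) * w / th)
}

#' Rotation angle between two orientations
#'
#' Geodesic angle of the relative rotation `qinv(a) qb`, in `[0, pi]`.
#'
#' @param a,b unit quaternions.
#' @return angle in radians.
#' @export
quat_angle <- function(a, b = quat_identity()) {
  check_quat(a); check_quat(b)
  d <- min(1, abs(sum(a * b)))
  2 * acos(d)
}

## ---- vectorised row-matrix variants (internal work-horses) ----

# Hamilton product of row matrices A, B (n x 4 each, or one a single quat).
qmul_rows <- function(A, B) {
  if (is.null(dim(A))) A <- matrix(A, nrow = max(1, NROW(B)), ncol = 4, byrow = TRUE)
  if (is.null(dim(B))) B <- matrix(B, nrow = nrow(A), ncol = 4, byrow = TRUE)
  cbind(A[, 1] * B[, 1] - A[, 2] * B[, 2] - A[, 3] * B[, 3] - A[, 4] * B[, 4],
        A[, 1] * B[, 2] + A[, 2] * B[, 1] + A[, 3] * B[, 4] - A[, 4] * B[, 3],
        A[, 1] * B[, 3] - A[, 2] * B[, 4] + A[, 3] * B[, 1] + A[, 4] * B[, 2],
        A[, 1] * B[, 4] + A[, 2] * B[, 3] - A[, 3] * B[, 2] + A[, 4] * B[, 1])
}

qinv_rows <- function(Q) {
  if (is.null(dim(Q))) Q <- matrix(Q, nrow = 1)
  cbind(Q[, 1], -Q[, 2], -Q[, 3], -Q[, 4]) / rowSums(Q^2)
}

# w >= 0 hemisphere for every row.
canonical_rows <- function(Q) {
  s <- sign(Q[, 1])
  s[s == 0] <- 1
  Q * s
}

# n x 4 quaternion rows -> n x 9 row-major rotation-matrix components
# (R11, R12, R13, R21, R22, R23, R31, R32, R33).
quat_to_matrix_rows <- function(Q) {
  if (is.null(dim(Q))) Q <- matrix(Q, nrow = 1)
  w <- Q[, 1]; x <- Q[, 2]; y <- Q[, 3]; z <- Q[, 4]
  cbind(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
        2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
        2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2))
}

# Rotate the unit x-axis by every quaternion row: first column of R.
rotate_x_rows <- function(Q) {
  if (is.null(dim(Q))) Q <- matrix(Q, nrow = 1)
  w <- Q[, 1]; x <- Q[, 2]; y <- Q[, 3]; z <- Q[, 4]
  cbind(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y))
}
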