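#' Quaternion algebra for rigid-body orientation
#'
#' Quaternions are stored w-first as numeric matrices with columns
#' `w, x, y, z` (Hamilton convention, one quaternion per row).  Orientation
#' quaternions map body-frame vectors into the world frame; the conjugate
#' therefore maps world-frame vectors into the body frame, which is the
#' direction an attached inertial sensor reads.
#'
#' @name quatmath
NULL

QUAT_COLS <- c("w", "x", "y", "z")

#' Build a quaternion matrix
#'
#' @param w,x,y,z numeric vectors of equal length (recycled scalars allowed).
#' @return an n x 4 numeric matrix with columns `w, x, y, z`.
#' @export
#' @examples
#' quat(1, 0, 0, 0)                 # identity rotation
#' quat(sqrt(0.5), 0, 0, sqrt(0.5)) # 90 degrees about +Z
quat <- function(w, x = 0, y = 0, z = 0) {
  q <- cbind(w = w, x = x, y = y, z = z)
  check_finite(q, "quaternion components")
  q
}

#' @rdname quat
#' @param q a length-4 vector or an n x 4 matrix.
#' @export
as_quat <- function(q) {
  if (is.null(dim(q))) {
    stopifnot(length(q) == 4L)
    q <- matrix(q, nrow = 1L)
  }
  stopifnot(ncol(q) == 4L)
  q <- as.matrix(q)
  colnames(q) <- QUAT_COLS
  check_finite(q, "quaternion components")
  q
}

check_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop("non-finite ", what, call. = FALSE)
  }
  invisible(x)
}

quat_norm <- function(q) {
  q <- as_quat(q)
  sqrt(rowSums(q^2))
}

#' Normalize quaternions to unit norm
#'
#' @param q quaternion matrix (rows) or length-4 vector.
#' @return matrix of unit quaternions (norm 1 within 1e-9).
#' @export
quat_normalize <- function(q) {
  q <- as_quat(q)
  n <- quat_norm(q)
  if (any(n < 1e-12)) stop("cannot normalize near-zero quaternion")
  q / n
}

stop_if_not_unit <- function(q, tol = 1e-6) {
  bad <- abs(quat_norm(q) - 1) > tol
  if (any(bad)) {
    stop(sprintf("non-unit quaternion (row %d, |norm - 1| = %.3g exceeds %g)",
                 which(bad)[1L], max(abs(quat_norm(q) - 1)), tol),
         call. = FALSE)
  }
  invisible(q)
}

#' Hamilton product of quaternions
#'
#' Row-wise product `a` %*% `b` in the Hamilton convention; composes the
#' rotation `b` followed by `a`.  Inputs need not be unit quaternions; the
#' product norm equals the product of norms.
#'
#' @param a,b quaternion matrices (rows broadcast if one has a single row).
#' @return quaternion matrix of the row-wise products.
#' @export
quat_product <- function(a, b) {
  a <- as_quat(a); b <- as_quat(b)
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  stopifnot(nrow(a) == nrow(b))
  strip_rownames(cbind(
    w = a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4],
    x = a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3],
    y = a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2],
    z = a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1]
  ))
}

strip_rownames <- function(m) {
  rownames(m) <- NULL
  m
}

#' Quaternion conjugate
#'
#' Negates the vector part.  For unit quaternions this is the inverse
#' rotation: `q` %*% `q*` is the identity.
#'
#' @param q quaternion matrix.
#' @return conjugated quaternion matrix.
#' @export
quat_conjugate <- function(q) {
  q <- as_quat(q)
  strip_rownames(cbind(w = q[, 1], x = -q[, 2], y = -q[, 3], z = -q[, 4]))
}

#' Rotate world-frame vectors into the body frame
#'
#' Computes the vector part of `q* (0, v) q`, i.e. expresses a world-frame
#' vector in the coordinates of the body whose orientation is `q`
#' (body-to-world).  Vector norms are preserved.
#'
#' @param q unit quaternion matrix (tolerance 1e-6), one row or one per
#'   vector row.
#' @param v numeric n x 3 matrix (or length-3 vector) of world-frame vectors.
#' @return n x 3 matrix of body-frame vectors.
#' @export
rotate_world_to_body <- function(q, v) {
  q <- as_quat(q)
  stop_if_not_unit(q)
  if (is.null(dim(v))) v <- matrix(v, nrow = 1L)
  stopifnot(ncol(v) == 3L)
  vq <- cbind(0, v)
  out <- quat_product(quat_product(quat_conjugate(q), vq), q)
  out <- out[, 2:4, drop = FALSE]
  colnames(out) <- c("x", "y", "z")
  strip_rownames(out)
}

#' Rotate body-frame vectors into the world frame (inverse of
#' [rotate_world_to_body()]).
#' @inheritParams rotate_world_to_body
#' @export
rotate_body_to_world <- function(q, v) {
  rotate_world_to_body(quat_conjugate(as_quat(q)), v)
}

#' Convert between unit quaternions and intrinsic Z-Y-X Euler angles
#'
#' The Euler convention is intrinsic yaw-pitch-roll (Z-Y-X): the rotation is
#' `qz(yaw) qy(pitch) qx(roll)`.  Angles are radians; yaw and roll lie in
#' (-pi, pi], pitch in \[-pi/2, pi/2\].  Within 1e-6 of the gimbal-lock
#' pitch of +/- pi/2 the yaw/roll split is resolved by setting roll = 0.
#' Away from gimbal lock the round trip reproduces the quaternion up to
#' global sign within 1e-9.
#'
#' Euler angles are returned wrapped: a rotation crossing the +/-180 degree
#' yaw boundary produces a jump of ~2 pi in the yaw channel.  This
#' discontinuity is deliberate - it is the artifact the inertial modality
#' transform removes.
#'
#' @param q unit quaternion matrix.
#' @return for `quat_to_euler`, an n x 3 matrix with columns
#'   `roll, pitch, yaw` (radians).
#' @export
quat_to_euler <- function(q) {
  q <- as_quat(q)
  stop_if_not_unit(q)
  q <- quat_normalize(q)
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  sinp <- 2 * (w * y - x * z)
  roll <- atan2(2 * (w * x + y * z), 1 - 2 * (x^2 + y^2))
  pitch <- asin(pmin(pmax(sinp, -1), 1))
  yaw <- atan2(2 * (w * z + x * y), 1 - 2 * (y^2 + z^2))
  # gimbal lock: pitch within 1e-6 of +/- pi/2 -> fix roll = 0, yaw carries
  # the whole Z rotation (yaw = 2 atan2(z, w) in that limit)
  locked <- abs(abs(sinp) - 1) < 2e-6 | abs(abs(pitch) - pi / 2) < 1e-6
  if (any(locked)) {
    roll[locked] <- 0
    yaw[locked] <- 2 * atan2(z[locked], w[locked])
  }
  strip_rownames(cbind(roll = roll, pitch = pitch, yaw = yaw))
}

#' @rdname quat_to_euler
#' @param e n x 3 matrix (or length-3 vector) of Euler angles with columns
#'   `roll, pitch, yaw` (radians).
#' @return for `euler_to_quat`, a unit quaternion matrix.
#' @export
euler_to_quat <- function(e) {
  if (is.null(dim(e))) e <- matrix(e, nrow = 1L)
  stopifnot(ncol(e) == 3L)
  check_finite(e, "Euler angles")
  hr <- e[, 1] / 2; hp <- e[, 2] / 2; hy <- e[, 3] / 2
  cr <- cos(hr); sr <- sin(hr)
  cp <- cos(hp); sp <- sin(hp)
  cy <- cos(hy); sy <- sin(hy)
  strip_rownames(cbind(
    w = cy * cp * cr + sy * sp * sr,
    x = cy * cp * sr - sy * sp * cr,
    y = cy * sp * cr + sy * cp * sr,
    z = sy * cp * cr - cy * sp * sr
  ))
}

# rotation of `angle[i]` about a fixed unit axis; vectorized over angle
quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  ha <- angle / 2
  s <- sin(ha)
  cbind(w = cos(ha), x = s * axis[1], y = s * axis[2], z = s * axis[3])
}
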