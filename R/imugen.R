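#' Pose-to-IMU modality transform
#'
#' Converts a uniformly sampled pose trajectory into the signals an inertial
#' measurement unit rigidly attached to the controller would report: linear
#' velocity and acceleration and angular velocity, all in the body frame.
#' Positions are differenced in the world frame and rotated into the body
#' frame through the orientation quaternion sandwich `q* (.) q`; angular
#' velocity comes from the quaternion derivative via the body-frame rate
#' matrix.  Derivatives use the forward difference
#' `f'(t) = (f(t+1) - f(t)) / dt`, with the last value duplicated so every
#' derived channel keeps the input length.
#'
#' @name imugen
NULL

#' Enforce sign continuity of a quaternion sequence
#'
#' `q` and `-q` encode the same rotation; recorded streams may flip sign
#' between samples, which corrupts finite differences.  Flips each
#' quaternion so consecutive dot products are nonnegative; the first sample
#' is kept as given.
#'
#' @param orientations n x 4 quaternion matrix.
#' @return n x 4 matrix, each row `+/- orientations[i, ]`.
#' @export
enforce_quat_continuity <- function(orientations) {
  q <- as_quat(orientations)
  if (nrow(q) == 0L) stop("empty orientation sequence")
  # cumulative sign: a flip at i propagates to all later samples
  d <- rowSums(q[-nrow(q), , drop = FALSE] * q[-1L, , drop = FALSE])
  sign_flip <- cumprod(c(1, ifelse(d < 0, -1, 1)))
  q * sign_flip
}

# forward difference with end-duplication; x is a matrix of series columns
forward_diff <- function(x, dt) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 samples to differentiate")
  if (dt <= 0) stop("dt must be positive")
  d <- (x[-1L, , drop = FALSE] - x[-nrow(x), , drop = FALSE]) / dt
  rbind(d, d[nrow(d), , drop = FALSE])
}

#' Forward-difference derivative of a quaternion sequence
#'
#' @param orientations continuity-enforced n x 4 quaternion matrix (n >= 2).
#' @param dt sample interval (s), > 0.
#' @return n x 4 matrix of component-wise derivatives (1/s); the last row
#'   duplicates row n - 1.
#' @export
quat_derivative <- function(orientations, dt) {
  forward_diff(as_quat(orientations), dt)
}

#' Body-frame velocity of a pose recording
#'
#' `v(t) = vec(q*(t) p'(t) q(t))`: the world-frame forward difference of
#' position, expressed in the body frame.  Norm-preserving, so `|v|` equals
#' the world-frame speed.
#'
#' @param rec a [pose_recording()].
#' @return n x 3 matrix of body-frame velocities (m/s).
#' @export
body_velocity <- function(rec) {
  stopifnot(inherits(rec, "pose_recording"))
  pdot <- forward_diff(rec$positions, 1 / rec$sample_rate)
  rotate_world_to_body(rec$orientations, pdot)
}

#' Body-frame acceleration of a pose recording
#'
#' `a(t) = vec(q*(t) p''(t) q(t))` with `p''` the forward difference applied
#' twice.  No gravity term is included by default: the transform models the
#' kinematic acceleration of the tracked body.  With `add_gravity = TRUE`
#' the world gravity vector (0, 0, -9.81) m/s^2 is rotated into the body
#' frame and subtracted, yielding accelerometer-style specific force.
#'
#' @param rec a [pose_recording()] with at least 3 samples.
#' @param add_gravity logical; include the gravitational reaction (default
#'   `FALSE`).
#' @return n x 3 matrix of body-frame accelerations (m/s^2).  The last two
#'   rows are padding artifacts of the double forward difference.
#' @export
body_acceleration <- function(rec, add_gravity = FALSE) {
  stopifnot(inherits(rec, "pose_recording"))
  dt <- 1 / rec$sample_rate
  pddot <- forward_diff(forward_diff(rec$positions, dt), dt)
  a <- rotate_world_to_body(rec$orientations, pddot)
  if (isTRUE(add_gravity)) {
    g <- rotate_world_to_body(rec$orientations, c(0, 0, -9.81))
    a <- a - g
  }
  a
}

#' Body-frame angular velocity from an orientation sequence
#'
#' `omega(t) = 2 M(q(t)) q'(t)` where `M(q)` is the 3 x 4 body-frame
#' quaternion-rate matrix
#' \deqn{M(q) = \begin{pmatrix} -x &  w &  z & -y \\
#'                              -y & -z &  w &  x \\
#'                              -z &  y & -x &  w \end{pmatrix}}
#' acting on `(w', x', y', z')`.  Algebraically identical to
#' `2 vec(q* q')`, the conjugate-product form used as the independent
#' cross-check in the test suite.
#'
#' @param orientations continuity-enforced unit quaternion matrix
#'   (tolerance 1e-6).
#' @param dt sample interval (s).
#' @return n x 3 matrix of body-frame angular velocities (rad/s).
#' @export
angular_velocity <- function(orientations, dt) {
  q <- as_quat(orientations)
  stop_if_not_unit(q, tol = 1e-6)
  dq <- quat_derivative(q, dt)
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  out <- 2 * cbind(
    x = -x * dq[, 1] + w * dq[, 2] + z * dq[, 3] - y * dq[, 4],
    y = -y * dq[, 1] - z * dq[, 2] + w * dq[, 3] + x * dq[, 4],
    z = -z * dq[, 1] + y * dq[, 2] - x * dq[, 3] + w * dq[, 4]
  )
  out
}

#' Zero-phase low-pass Butterworth filter
#'
#' Forward-backward 4th-order (by default) Butterworth low-pass per channel.
#' The two passes cancel phase distortion (no time shift of gesture
#' features) and square the magnitude response, so the gain at the cutoff is
#' 0.5.  Edge transients are suppressed with odd-reflection padding and
#' steady-state initial filter conditions, so a constant channel passes
#' through unchanged.
#'
#' @param x numeric vector or n x C matrix of uniformly sampled channels.
#' @param cutoff cutoff frequency (Hz), must be below the Nyquist rate.
#' @param sample_rate sampling frequency (Hz).
#' @param order Butterworth order per pass (default 4).
#' @return filtered object of the same shape.
#' @export
lowpass_filter <- function(x, cutoff, sample_rate, order = 4) {
  if (cutoff >= sample_rate / 2) {
    stop(sprintf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 cutoff, sample_rate / 2))
  }
  if (cutoff <= 0) stop("cutoff must be positive")
  bf <- signal::butter(order, cutoff / (sample_rate / 2), type = "low")
  vec_in <- is.null(dim(x))
  x <- as.matrix(x)
  out <- apply(x, 2L, filtfilt_padded, b = bf$b, a = bf$a)
  out <- matrix(out, nrow = nrow(x), dimnames = dimnames(x))
  if (vec_in) out[, 1L] else out
}

# forward-backward IIR pass with odd reflection padding and steady-state
# initial conditions at both ends (matched-step initialization)
filtfilt_padded <- function(x, b, a) {
  n <- length(x)
  npad <- min(n - 1L, 3L * (max(length(a), length(b)) - 1L))
  zi <- lfilter_zi(b, a)
  ext <- c(2 * x[1L] - x[seq(npad + 1L, 2L)], x,
           2 * x[n] - x[seq(n - 1L, n - npad)])
  y <- iir_df2t(b, a, ext, zi * ext[1L])
  y <- rev(iir_df2t(b, a, rev(y), zi * y[length(y)]))
  y[(npad + 1L):(npad + n)]
}

# steady-state filter delay states for a unit step (scipy lfilter_zi)
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b))) / a[1L]
  a <- c(a, rep(0, n - length(a))) / a[1L]
  companion <- rbind(-a[2:n], cbind(diag(1, n - 2L), 0))
  solve(diag(n - 1L) - t(companion), b[2:n] - a[2:n] * b[1L])
}

# direct-form-II-transposed IIR filter with explicit initial state
iir_df2t <- function(b, a, x, zi) {
  nz <- length(zi)
  y <- numeric(length(x))
  z <- zi
  for (i in seq_along(x)) {
    y[i] <- b[1L] * x[i] + z[1L]
    if (nz > 1L) {
      z[seq_len(nz - 1L)] <- b[2:nz] * x[i] + z[2:nz] - a[2:nz] * y[i]
    }
    z[nz] <- b[nz + 1L] * x[i] - a[nz + 1L] * y[i]
  }
  y
}

#' Transform a pose recording into synthetic IMU channels
#'
#' Full pipeline: quaternion sign-continuity enforcement, forward-difference
#' derivatives, rotation into the body frame, and optional zero-phase
#' low-pass conditioning of the acceleration and angular-velocity channels.
#' The output is invariant to a rigid re-orientation of the world frame.
#'
#' @param rec a [pose_recording()].
#' @param cutoff low-pass cutoff in Hz applied to acceleration and angular
#'   velocity, or `NULL` (default) for no filtering.  Typical values: 3 or 6.
#' @param order Butterworth order (default 4).
#' @param add_gravity passed to [body_acceleration()].
#' @return a [kinematic_series()].
#' @export
#' @examples
#' t <- seq(0, 1, by = 1 / 60)
#' rec <- pose_recording(
#'   positions = cbind(sin(2 * pi * t), 0, 0),
#'   orientations = quat(1, 0, 0, 0)[rep(1, length(t)), ],
#'   sample_rate = 60
#' )
#' ks <- transform_recording(rec, cutoff = 6)
transform_recording <- function(rec, cutoff = NULL, order = 4,
                                add_gravity = FALSE) {
  stopifnot(inherits(rec, "pose_recording"))
  q <- enforce_quat_continuity(rec$orientations)
  rec_c <- rec
  rec_c$orientations <- q
  v <- body_velocity(rec_c)
  a <- body_acceleration(rec_c, add_gravity = add_gravity)
  omega <- angular_velocity(q, 1 / rec$sample_rate)
  if (!is.null(cutoff)) {
    a <- lowpass_filter(a, cutoff, rec$sample_rate, order)
    omega <- lowpass_filter(omega, cutoff, rec$sample_rate, order)
  }
  kinematic_series(v, a, omega, rec$sample_rate)
}
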