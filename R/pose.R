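#' Pose recordings and derived kinematic series
#'
#' A `pose_recording` holds one uniformly sampled trial of 6-DoF controller
#' pose: world-frame positions (meters) and body-to-world unit quaternions.
#' A `kinematic_series` holds the derived body-frame velocity (m/s),
#' acceleration (m/s^2) and angular velocity (rad/s) channels.
#'
#' @name pose
NULL

#' Construct a pose recording
#'
#' @param positions n x 3 matrix of world-frame positions (m).
#' @param orientations n x 4 matrix of unit quaternions (w-first,
#'   body-to-world), unit within 1e-6; re-normalized on construction.
#' @param sample_rate sampling frequency (Hz), > 0.
#' @return object of class `pose_recording` with elements `positions`,
#'   `orientations`, `sample_rate`, `duration` ((n - 1) / sample_rate, s).
#' @export
pose_recording <- function(positions, orientations, sample_rate) {
  positions <- as.matrix(positions)
  orientations <- as_quat(orientations)
  if (nrow(positions) != nrow(orientations)) {
    stop("positions and orientations must have the same number of samples")
  }
  if (nrow(positions) < 3L) stop("a pose recording needs at least 3 samples")
  stopifnot(ncol(positions) == 3L)
  check_finite(positions, "positions")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0) {
    stop("sample_rate must be a single positive number")
  }
  stop_if_not_unit(orientations, tol = 1e-6)
  colnames(positions) <- c("x", "y", "z")
  structure(
    list(
      positions = positions,
      orientations = quat_normalize(orientations),
      sample_rate = sample_rate,
      duration = (nrow(positions) - 1L) / sample_rate
    ),
    class = "pose_recording"
  )
}

#' @export
print.pose_recording <- function(x, ...) {
  cat(sprintf("<pose_recording> %d samples @ %g Hz (%.3f s)\n",
              nrow(x$positions), x$sample_rate, x$duration))
  invisible(x)
}

#' @export
length.pose_recording <- function(x) nrow(x$positions)

#' Construct a kinematic series
#'
#' Container for the body-frame channels derived from a pose recording.
#'
#' @param velocity,acceleration,angular_velocity n x 3 matrices (m/s,
#'   m/s^2, rad/s), equal row counts, finite.
#' @param sample_rate sampling frequency (Hz).
#' @return object of class `kinematic_series`.
#' @export
kinematic_series <- function(velocity, acceleration, angular_velocity,
                             sample_rate) {
  chans <- list(velocity = as.matrix(velocity),
                acceleration = as.matrix(acceleration),
                angular_velocity = as.matrix(angular_velocity))
  n <- unique(vapply(chans, nrow, 1L))
  if (length(n) != 1L) stop("kinematic channels must share length")
  for (nm in names(chans)) {
    stopifnot(ncol(chans[[nm]]) == 3L)
    check_finite(chans[[nm]], nm)
    colnames(chans[[nm]]) <- c("x", "y", "z")
  }
  structure(c(chans, list(sample_rate = sample_rate)),
            class = "kinematic_series")
}

#' @export
print.kinematic_series <- function(x, ...) {
  cat(sprintf("<kinematic_series> %d samples @ %g Hz (v, a, omega)\n",
              nrow(x$velocity), x$sample_rate))
  invisible(x)
}
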