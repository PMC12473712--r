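#' Recording and manifest I/O
#'
#' Two plain CSV dialects are used throughout:
#' * pose CSV - header `t,px,py,pz,qw,qx,qy,qz`; time in seconds
#'   (uniformly sampled, jitter tolerance 1e-6 s), positions in meters,
#'   unit quaternions w-first;
#' * IMU CSV - header `t,acc_x,acc_y,acc_z,gyr_x,gyr_y,gyr_z`
#'   (m/s^2 and rad/s).
#'
#' A dataset manifest is a CSV with columns
#' `subject_id,day,trial,device,path`; `path` is relative to the manifest's
#' directory.
#'
#' @name datasets_io
NULL

POSE_HEADER <- c("t", "px", "py", "pz", "qw", "qx", "qy", "qz")
IMU_HEADER <- c("t", "acc_x", "acc_y", "acc_z", "gyr_x", "gyr_y", "gyr_z")
MANIFEST_HEADER <- c("subject_id", "day", "trial", "device", "path")

check_schema <- function(df, expected, path) {
  if (!identical(names(df), expected)) {
    stop(sprintf(
      "schema mismatch in '%s': expected columns [%s], found [%s]",
      path, paste(expected, collapse = ","), paste(names(df), collapse = ",")
    ), call. = FALSE)
  }
  invisible(df)
}

check_uniform_time <- function(t, path, jitter = 1e-6) {
  if (length(t) < 2L) stop("fewer than 2 samples in '", path, "'")
  dt <- diff(t)
  if (any(dt <= 0) || max(abs(dt - stats::median(dt))) > jitter) {
    stop(sprintf(
      "non-uniform sampling in '%s': time steps deviate by %.3g s (tolerance %g s); resample before use",
      path, max(abs(dt - stats::median(dt))), jitter
    ), call. = FALSE)
  }
  stats::median(dt)
}

#' Write / read a pose recording as CSV
#'
#' @param rec a [pose_recording()].
#' @param path file path.
#' @return `read_pose_csv` returns a [pose_recording()]; quaternions within
#'   1e-3 of unit norm are re-normalized, anything further off is rejected.
#' @export
write_pose_csv <- function(rec, path) {
  stopifnot(inherits(rec, "pose_recording"))
  n <- nrow(rec$positions)
  df <- data.frame((seq_len(n) - 1L) / rec$sample_rate,
                   rec$positions, rec$orientations)
  names(df) <- POSE_HEADER
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pose_csv
#' @export
read_pose_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  check_schema(df, POSE_HEADER, path)
  dt <- check_uniform_time(df$t, path)
  q <- as.matrix(df[, c("qw", "qx", "qy", "qz")])
  norms <- sqrt(rowSums(q^2))
  if (any(abs(norms - 1) > 1e-3)) {
    stop(sprintf(
      "non-unit quaternion in '%s' (row %d, norm %.4f); not a valid orientation stream",
      path, which(abs(norms - 1) > 1e-3)[1L], norms[which.max(abs(norms - 1))]
    ), call. = FALSE)
  }
  pose_recording(as.matrix(df[, c("px", "py", "pz")]), q / norms,
                 sample_rate = 1 / dt)
}

#' Write / read synthetic IMU channels as CSV
#'
#' @param ks a [kinematic_series()] (velocity is not serialized; the IMU
#'   dialect carries accelerometer and gyroscope channels only).
#' @param path file path.
#' @return `read_imu_csv` returns a list with `acc`, `gyr` (n x 3 matrices)
#'   and `sample_rate`.
#' @export
write_imu_csv <- function(ks, path) {
  stopifnot(inherits(ks, "kinematic_series"))
  n <- nrow(ks$acceleration)
  df <- data.frame((seq_len(n) - 1L) / ks$sample_rate,
                   ks$acceleration, ks$angular_velocity)
  names(df) <- IMU_HEADER
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_imu_csv
#' @export
read_imu_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  check_schema(df, IMU_HEADER, path)
  dt <- check_uniform_time(df$t, path)
  list(acc = as.matrix(df[, 2:4]), gyr = as.matrix(df[, 5:7]),
       sample_rate = 1 / dt)
}

#' Write / read a dataset manifest
#'
#' @param manifest data frame with columns
#'   `subject_id, day, trial, device, path`.
#' @param path manifest CSV path.
#' @param check_paths if `TRUE` (default on read), verify that every
#'   referenced recording file exists relative to the manifest directory.
#' @return `read_manifest` returns the validated manifest data frame with
#'   attribute `base_dir` set to the manifest's directory.
#' @export
write_manifest <- function(manifest, path) {
  check_schema(manifest[MANIFEST_HEADER], MANIFEST_HEADER, path)
  utils::write.csv(manifest[MANIFEST_HEADER], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(subject_id = "character",
                                       device = "character",
                                       path = "character"))
  check_schema(df, MANIFEST_HEADER, path)
  key <- do.call(paste, c(df[c("subject_id", "day", "trial", "device")],
                          sep = "\r"))
  if (anyDuplicated(key)) {
    stop("duplicate (subject_id, day, trial, device) rows in manifest")
  }
  base_dir <- dirname(path)
  if (isTRUE(check_paths)) {
    missing <- !file.exists(file.path(base_dir, df$path))
    if (any(missing)) {
      stop("manifest references missing files: ",
           paste(utils::head(df$path[missing], 5L), collapse = ", "))
    }
  }
  attr(df, "base_dir") <- base_dir
  df
}
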