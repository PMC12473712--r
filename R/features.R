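#' Modality assembly and normalization
#'
#' Turns a manifest of pose recordings into fixed-length feature tensors
#' for the classifiers.  Four 3-channel modalities are available:
#' * `POS` - raw world-frame positions (m);
#' * `EULER` - wrapped intrinsic Z-Y-X Euler angles (rad), deliberately
#'   left discontinuous at the +/-180 degree boundary;
#' * `ACC` - synthetic body-frame accelerometer (m/s^2);
#' * `GYRO` - synthetic body-frame gyroscope (rad/s).
#'
#' Channels are linearly resampled to the layout's length (128 samples for
#' the stacked single-input layout, 100 per branch for the two-branch
#' layout) and z-scored per channel with statistics fitted on the training
#' split only.
#'
#' @name features
NULL

MODALITY_SETS <- c("POS", "EULER", "ACC", "GYRO")

#' Modality configuration
#'
#' @param channel_sets character vector drawn from
#'   `c("POS", "EULER", "ACC", "GYRO")`; order defines channel order.
#' @param lowpass_cutoff cutoff (Hz) for the ACC/GYRO transform, or `NULL`
#'   for unfiltered signals.
#' @param layout `"stacked"` (one `stacked_length x 3k` array per trial) or
#'   `"branched"` (one `branch_length x 3` array per channel set, 1-2 sets).
#' @param stacked_length,branch_length target lengths in samples.
#' @return object of class `modality_config`.
#' @export
modality_config <- function(channel_sets, lowpass_cutoff = NULL,
                            layout = c("stacked", "branched"),
                            stacked_length = 128, branch_length = 100) {
  layout <- match.arg(layout)
  channel_sets <- toupper(channel_sets)
  bad <- setdiff(channel_sets, MODALITY_SETS)
  if (length(bad)) {
    stop("unknown channel set(s): ", paste(bad, collapse = ", "),
         " (expected POS, EULER, ACC, GYRO)")
  }
  if (length(channel_sets) < 1L) stop("at least one channel set required")
  if (layout == "branched" && length(channel_sets) > 2L) {
    stop("branched layout supports 1-2 channel sets")
  }
  if (!is.null(lowpass_cutoff)) stopifnot(lowpass_cutoff > 0)
  structure(
    list(channel_sets = channel_sets, lowpass_cutoff = lowpass_cutoff,
         layout = layout, stacked_length = stacked_length,
         branch_length = branch_length),
    class = "modality_config"
  )
}

#' Read a modality configuration from YAML
#'
#' Keys mirror [modality_config()] arguments (`channel_sets`,
#' `lowpass_cutoff`, `layout`, `stacked_length`, `branch_length`).
#'
#' @param path YAML file.
#' @return a `modality_config`.
#' @export
read_modality_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(modality_config, cfg)
}

#' Linearly resample multichannel series to a target length
#'
#' Per-channel linear interpolation on a uniform grid spanning the same
#' time interval; endpoints are preserved exactly, and a linear ramp stays
#' exactly linear.
#'
#' @param x n x C numeric matrix (n >= 2) or numeric vector.
#' @param target_len output length M >= 2.
#' @return M x C matrix (or length-M vector for vector input).
#' @export
resample_channels <- function(x, target_len) {
  vec_in <- is.null(dim(x))
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 samples to resample")
  if (target_len < 2L) stop("target length must be at least 2")
  src <- seq(0, 1, length.out = nrow(x))
  dst <- seq(0, 1, length.out = target_len)
  out <- apply(x, 2L, function(col) stats::approx(src, col, xout = dst)$y)
  out <- matrix(out, nrow = target_len)
  colnames(out) <- colnames(x)
  if (vec_in) out[, 1L] else out
}

modality_channels <- function(rec, set, cutoff, add_gravity = FALSE) {
  switch(set,
    POS = rec$positions,
    EULER = quat_to_euler(enforce_quat_continuity(rec$orientations)),
    ACC = transform_recording(rec, cutoff = cutoff,
                              add_gravity = add_gravity)$acceleration,
    GYRO = transform_recording(rec, cutoff = cutoff)$angular_velocity,
    stop("unknown channel set: ", set)
  )
}

#' Assemble per-trial feature tensors from a manifest
#'
#' Reads every recording in the manifest, derives the configured channel
#' sets, and resamples them to the layout length.  Stacked layout returns
#' one `n x L x 3k` array; branched layout returns one `n x L x 3` array
#' per channel set.
#'
#' @param manifest manifest data frame (see [read_manifest()]).
#' @param modality a [modality_config()].
#' @param base_dir directory that manifest paths are relative to; defaults
#'   to the manifest's `base_dir` attribute.
#' @param add_gravity passed to the ACC transform.
#' @return object of class `feature_set`: list with either `x` (stacked
#'   array) or `branches` (list of arrays), plus `labels` (factor of
#'   subject ids), `days` (integer vector) and `modality`.
#' @export
assemble_features <- function(manifest, modality, base_dir = NULL,
                              add_gravity = FALSE) {
  stopifnot(inherits(modality, "modality_config"))
  if (is.null(base_dir)) base_dir <- attr(manifest, "base_dir")
  if (is.null(base_dir)) base_dir <- "."
  n <- nrow(manifest)
  len <- if (modality$layout == "stacked") modality$stacked_length
         else modality$branch_length
  sets <- modality$channel_sets
  per_set <- lapply(sets, function(s) array(NA_real_, c(n, len, 3L)))
  names(per_set) <- sets
  for (i in seq_len(n)) {
    rec <- read_pose_csv(file.path(base_dir, manifest$path[i]))
    for (s in sets) {
      ch <- modality_channels(rec, s, modality$lowpass_cutoff,
                              add_gravity = add_gravity)
      per_set[[s]][i, , ] <- resample_channels(ch, len)
    }
  }
  out <- list(
    labels = factor(manifest$subject_id),
    days = as.integer(manifest$day),
    modality = modality
  )
  if (modality$layout == "stacked") {
    x <- array(NA_real_, c(n, len, 3L * length(sets)))
    for (k in seq_along(sets)) {
      x[, , (3L * k - 2L):(3L * k)] <- per_set[[k]]
    }
    out$x <- x
  } else {
    out$branches <- per_set
  }
  structure(out, class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  dims <- if (!is.null(x$x)) paste(dim(x$x), collapse = " x ")
          else paste(vapply(x$branches,
                            function(b) paste(dim(b), collapse = " x "), ""),
                     collapse = " | ")
  cat(sprintf("<feature_set> %s; %d classes\n", dims, nlevels(x$labels)))
  invisible(x)
}

#' Z-score features with statistics from the training rows only
#'
#' Per-channel mean and SD are computed over the training rows (all time
#' steps pooled) and applied to every row, so no test-split statistic leaks
#' into the representation the model sees.
#'
#' @param features a `feature_set` from [assemble_features()].
#' @param train_idx integer indices of the training rows.
#' @return the feature set with channels standardized; fitted statistics
#'   are stored in the `norm_stats` element.
#' @export
normalize_features <- function(features, train_idx) {
  stopifnot(inherits(features, "feature_set"), length(train_idx) >= 1L)
  zscore <- function(arr) {
    nc <- dim(arr)[3L]
    mu <- numeric(nc); sd <- numeric(nc)
    for (c in seq_len(nc)) {
      tr <- arr[train_idx, , c]
      mu[c] <- mean(tr)
      sd[c] <- stats::sd(as.vector(tr))
      if (!is.finite(sd[c]) || sd[c] < 1e-12) sd[c] <- 1
      arr[, , c] <- (arr[, , c] - mu[c]) / sd[c]
    }
    list(arr = arr, mu = mu, sd = sd)
  }
  if (!is.null(features$x)) {
    z <- zscore(features$x)
    features$x <- z$arr
    features$norm_stats <- list(mu = z$mu, sd = z$sd)
  } else {
    stats_list <- list()
    for (nm in names(features$branches)) {
      z <- zscore(features$branches[[nm]])
      features$branches[[nm]] <- z$arr
      stats_list[[nm]] <- list(mu = z$mu, sd = z$sd)
    }
    features$norm_stats <- stats_list
  }
  features
}

# row subset of a feature set
subset_features <- function(features, idx) {
  if (!is.null(features$x)) {
    features$x <- features$x[idx, , , drop = FALSE]
  } else {
    features$branches <- lapply(features$branches,
                                function(b) b[idx, , , drop = FALSE])
  }
  features$labels <- features$labels[idx]
  features$days <- features$days[idx]
  features
}
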