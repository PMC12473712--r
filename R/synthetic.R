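#' Seeded generator of subject-distinct VR throw gestures
#'
#' Emulates the structure of overhand virtual-basketball throws recorded by
#' a right-hand VR controller: one dominant reach along the world X axis
#' with a min-jerk speed profile, a wrist sweep about a subject-specific
#' near-Y axis, a base yaw close to the +/-180 degree boundary (so the
#' Euler-angle representation of orientation is discontinuous while the
#' underlying rotation is smooth), temporally correlated trial noise, and a
#' seeded between-day parameter drift.
#'
#' @name synthetic
NULL

# deterministic sub-stream seed; all intermediates stay exact in doubles
derive_seed <- function(master, ...) {
  s <- as.double(master) %% 2147483647
  for (i in c(...)) {
    s <- (s * 48271 + as.double(i) * 9973 + 1) %% 2147483647
  }
  as.integer(s)
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lower | x >= upper)
  while (length(bad) > 0L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x <= lower | x >= upper)
  }
  x
}

#' Synthetic dataset configuration
#'
#' Defaults mirror the motivating corpus: 41 subjects, 10 trials per day,
#' 2 recording days, 3-second trials at 45 Hz (135 frames).  Noise scales
#' are stated in physical units: `trial_noise_pos` is the RMS of the
#' smoothed positional execution/tracking noise per axis (m),
#' `trial_noise_angle` the RMS orientation perturbation (rad), and
#' `day_drift_scale` the relative SD of the per-day multiplicative drift
#' applied to each subject's motion parameters.
#'
#' @param n_subjects,trials_per_day,n_days counts (>= 1).
#' @param sample_rate Hz.
#' @param duration trial length (s); `duration * sample_rate >= 16`.
#' @param trial_noise_pos RMS positional noise per axis (m).
#' @param trial_noise_angle RMS orientation noise (rad).
#' @param day_drift_scale relative between-day parameter drift.
#' @param seed master seed; every random draw derives from it.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 41, trials_per_day = 10, n_days = 2,
                         sample_rate = 45, duration = 3,
                         trial_noise_pos = 0.01,
                         trial_noise_angle = 0.02,
                         day_drift_scale = 0.05,
                         seed = 1) {
  stopifnot(n_subjects >= 1, trials_per_day >= 1, n_days >= 1,
            sample_rate > 0, duration > 0,
            trial_noise_pos >= 0, trial_noise_angle >= 0,
            day_drift_scale >= 0)
  if (duration * sample_rate < 16) {
    stop("duration * sample_rate must be at least 16 samples")
  }
  structure(as.list(environment()), class = "synth_config")
}

#' Draw subject-specific motion parameters
#'
#' Parameters are drawn independently per subject from truncated normal /
#' scaled beta distributions: reach amplitude N(0.9, 0.1^2) m truncated
#' above 0.3; movement duration N(1.4, 0.15^2) s truncated to (0.5, 2.5);
#' velocity-peak fraction 0.3 + 0.4 Beta(2, 2); wrist sweep angle
#' N(2.44, 0.26^2) rad (about 140 +/- 15 degrees) about a unit axis tilted
#' up to 25 degrees from +Y; lateral path curvature N(0, 0.05^2) m.  The
#' base yaw is placed so the trial's yaw trajectory straddles the +/-pi
#' boundary (the yaw contributed by the wrist sweep is centered on pi).
#'
#' @param n number of subjects.
#' @param seed integer seed; draws are deterministic given `(n, seed)`.
#' @return data frame with one row per subject (`subject_id`,
#'   `reach_amplitude`, `movement_duration`, `peak_fraction`,
#'   `wrist_sweep_angle`, `axis_x/y/z`, `lateral_curvature`, `base_yaw`).
#' @export
draw_subjects <- function(n, seed) {
  stopifnot(n >= 1)
  with_seed(derive_seed(seed, 101L), {
    reach <- rnorm_trunc(n, 0.9, 0.1, lower = 0.3)
    md <- rnorm_trunc(n, 1.4, 0.15, lower = 0.5, upper = 2.5)
    peak <- 0.3 + 0.4 * stats::rbeta(n, 2, 2)
    sweep <- rnorm_trunc(n, 2.44, 0.26, lower = 0.5)
    lat <- stats::rnorm(n, 0, 0.05)
    # wrist axis + base yaw: the base yaw centers the +/-pi boundary on a
    # moderate-rate segment of the sweep's yaw trajectory, so every trial
    # crosses the Euler wrap transversally.  Axes whose yaw margin is too
    # small to survive trial noise are rejected and redrawn (truncation of
    # the axis distribution, like the truncated normals above).
    ax <- az <- ay <- base_yaw <- numeric(n)
    for (i in seq_len(n)) {
      best_margin <- -1
      for (try in 1:40) {
        tilt <- stats::runif(1, 12, 25) * pi / 180
        zshare <- stats::runif(1, 0.6, 1)
        axis <- c(sin(tilt) * sqrt(1 - zshare^2) * sample(c(-1, 1), 1),
                  cos(tilt),
                  sin(tilt) * zshare * sample(c(-1, 1), 1))
        cal <- calibrate_base_yaw(axis, sweep[i])
        if (cal$margin > best_margin) {
          best_margin <- cal$margin
          ax[i] <- axis[1]; ay[i] <- axis[2]; az[i] <- axis[3]
          base_yaw[i] <- cal$base_yaw
        }
        if (best_margin >= 0.35) break
      }
    }
    data.frame(
      subject_id = sprintf("S%02d", seq_len(n)),
      reach_amplitude = reach,
      movement_duration = md,
      peak_fraction = peak,
      wrist_sweep_angle = sweep,
      axis_x = ax, axis_y = ay, axis_z = az,
      lateral_curvature = lat,
      base_yaw = base_yaw,
      stringsAsFactors = FALSE
    )
  })
}

wrap_pi <- function(a) ((a + pi) %% (2 * pi)) - pi

# choose the base yaw that centers the +/-pi boundary on the longest
# moderate-rate segment of the sweep's own yaw contribution; returns the
# half-extent of that segment as the crossing margin (rad)
calibrate_base_yaw <- function(axis, sweep_angle) {
  sg <- seq(0, 1, length.out = 201)
  yp <- quat_to_euler(quat_from_axis_angle(axis, sweep_angle * sg))[, "yaw"]
  steps <- wrap_pi(diff(yp))
  yu <- cumsum(c(yp[1L], steps))  # unwrapped continuous yaw path
  dy <- abs(steps)
  # moderate rate: fast enough to clear trial noise, slow enough that the
  # wrapped jump at the crossing exceeds pi; near-gimbal bursts of the
  # Euler decomposition (very large dy) are excluded
  good <- dy > 0.01 & dy < 0.08
  if (!any(good)) good <- dy < 0.2 & dy > 0
  if (!any(good)) return(list(base_yaw = wrap_pi(pi - yu[101L]), margin = 0))
  runs <- rle(good)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  seg <- which(runs$values)
  extents <- abs(yu[ends[seg] + 1L] - yu[starts[seg]])
  best <- seg[which.max(extents)]
  mid <- (yu[starts[best]] + yu[ends[best] + 1L]) / 2
  list(base_yaw = wrap_pi(pi - mid), margin = max(extents) / 2)
}

min_jerk <- function(u) 10 * u^3 - 15 * u^4 + 6 * u^5

#' Generate one synthetic throw trial
#'
#' Builds the noiseless subject template (min-jerk reach + wrist sweep),
#' applies the seeded per-day multiplicative parameter drift, then adds
#' smoothed (low-pass filtered) white noise to positions and small
#' random-axis rotation noise to orientations.  Fully deterministic given
#' `(params, day, trial, cfg)`.
#'
#' @param params one row of [draw_subjects()] (data frame or list).
#' @param day,trial 1-based indices selecting the noise/drift sub-streams.
#' @param cfg a [synth_config()].
#' @return a [pose_recording()] of `round(duration * sample_rate)` samples.
#' @export
generate_trial <- function(params, day, trial, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  p <- as.list(params)
  subj_num <- as.integer(sub("^S", "", p$subject_id))

  # between-day drift: one multiplicative factor per motion parameter.
  # The wrist sweep angle is deliberately kept fixed across days so the
  # yaw trajectory stays calibrated on the +/-pi boundary; timing and
  # amplitude parameters carry the day effect.
  if (cfg$day_drift_scale > 0) {
    z <- with_seed(derive_seed(cfg$seed, 211L, subj_num, day),
                   stats::rnorm(4))
    f <- 1 + cfg$day_drift_scale * z
    p$reach_amplitude <- max(0.2, p$reach_amplitude * f[1])
    p$movement_duration <- min(max(p$movement_duration * f[2], 0.4),
                               cfg$duration * 0.97)
    p$peak_fraction <- min(max(p$peak_fraction * f[3], 0.1), 0.9)
    p$lateral_curvature <- p$lateral_curvature * f[4]
  }

  n <- round(cfg$duration * cfg$sample_rate)
  t <- (seq_len(n) - 1L) / cfg$sample_rate
  tau <- pmin(t / p$movement_duration, 1)
  # smooth monotone quadratic warp placing the velocity peak at
  # peak_fraction of the movement (the unwarped min-jerk peak is at 1/2)
  k <- (0.5 - p$peak_fraction) / (p$peak_fraction * (1 - p$peak_fraction))
  u <- pmin((1 + k) * tau - k * tau^2, 1)
  s <- min_jerk(u)

  start <- c(0.10, -0.20, 1.30)  # controller held near shoulder height
  pos <- cbind(
    x = start[1] + p$reach_amplitude * s,
    y = start[2] + p$lateral_curvature * sin(pi * s),
    z = start[3] + 0.15 * p$reach_amplitude * sin(pi * s)
  )
  axis <- c(p$axis_x, p$axis_y, p$axis_z)
  q <- quat_product(
    euler_to_quat(c(0, 0, p$base_yaw)),
    quat_from_axis_angle(axis, p$wrist_sweep_angle * s)
  )

  if (cfg$trial_noise_pos > 0 || cfg$trial_noise_angle > 0) {
    q_noise <- NULL
    with_seed(derive_seed(cfg$seed, 307L, subj_num, day, trial), {
      if (cfg$trial_noise_pos > 0) {
        pos <- pos + smooth_noise(n, 3L, cfg$sample_rate, cfg$trial_noise_pos)
      }
      if (cfg$trial_noise_angle > 0) {
        rv <- smooth_noise(n, 3L, cfg$sample_rate, cfg$trial_noise_angle)
        q_noise <- rotvec_to_quat(rv)
      }
    })
    if (!is.null(q_noise)) q <- quat_product(q, q_noise)
  }

  pose_recording(pos, quat_normalize(q), cfg$sample_rate)
}

# temporally correlated noise: low-pass filtered white noise, rescaled to
# the requested per-column RMS (controller tracking error is not white)
smooth_noise <- function(n, ncol, sample_rate, rms) {
  x <- matrix(stats::rnorm(n * ncol), n, ncol)
  cutoff <- min(2, 0.4 * sample_rate)
  x <- lowpass_filter(x, cutoff, sample_rate, order = 2)
  scale <- rms / pmax(sqrt(colMeans(x^2)), 1e-12)
  x * rep(scale, each = n)
}

# exponential map: rotation-vector rows -> unit quaternions
rotvec_to_quat <- function(r) {
  ang <- sqrt(rowSums(r^2))
  k <- ifelse(ang < 1e-12, 0.5, sin(ang / 2) / pmax(ang, 1e-300))
  cbind(w = cos(ang / 2), x = r[, 1] * k, y = r[, 2] * k, z = r[, 3] * k)
}

#' Generate a full synthetic dataset on disk
#'
#' Writes one pose CSV per (subject, day, trial) plus a `manifest.csv`
#' indexing them.  Reproducible from `cfg$seed` alone.
#'
#' @param cfg a [synth_config()].
#' @param out_dir writable destination directory (created if missing).
#' @return the manifest data frame (invisibly readable back with
#'   [read_manifest()]), with columns
#'   `subject_id, day, trial, device, path`.
#' @export
#' @examples
#' cfg <- synth_config(n_subjects = 2, trials_per_day = 2, seed = 7)
#' man <- generate_dataset(cfg, file.path(tempdir(), "demo"))
#' nrow(man)  # 2 subjects x 2 days x 2 trials = 8
generate_dataset <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "synth_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  subjects <- draw_subjects(cfg$n_subjects, cfg$seed)
  rows <- vector("list", cfg$n_subjects * cfg$n_days * cfg$trials_per_day)
  i <- 0L
  for (si in seq_len(cfg$n_subjects)) {
    for (day in seq_len(cfg$n_days)) {
      for (trial in seq_len(cfg$trials_per_day)) {
        rec <- generate_trial(subjects[si, ], day, trial, cfg)
        fname <- sprintf("%s_d%d_t%02d.csv", subjects$subject_id[si],
                         day, trial)
        write_pose_csv(rec, file.path(out_dir, fname))
        i <- i + 1L
        rows[[i]] <- data.frame(
          subject_id = subjects$subject_id[si], day = day, trial = trial,
          device = "synthetic", path = fname, stringsAsFactors = FALSE
        )
      }
    }
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  attr(manifest, "base_dir") <- out_dir
  manifest
}
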