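test_that("subject draws are deterministic, distinct, and on-distribution", {
  expect_identical(draw_subjects(2, 7), draw_subjects(2, 7))
  s <- draw_subjects(41, 1)
  expect_equal(nrow(unique(s[, -1])), 41)
  expect_true(all(s$reach_amplitude > 0.3))
  expect_true(all(s$movement_duration > 0.5 & s$movement_duration < 2.5))
  expect_true(all(s$peak_fraction > 0.3 & s$peak_fraction < 0.7))
  axes <- as.matrix(s[, c("axis_x", "axis_y", "axis_z")])
  expect_lt(max(abs(sqrt(rowSums(axes^2)) - 1)), 1e-9)
  expect_true(all(axes[, 2] > cos(25 * pi / 180) - 1e-9))  # tilt <= 25 deg
  big <- draw_subjects(500, 3)
  se <- 0.1 / sqrt(500)
  expect_lt(abs(mean(big$reach_amplitude) - 0.9), 3 * se)
})

test_that("noiseless template is reproducible with exact reach displacement", {
  s <- draw_subjects(2, 7)
  cfg0 <- synth_config(n_subjects = 2, trial_noise_pos = 0,
                       trial_noise_angle = 0, day_drift_scale = 0, seed = 7)
  a <- generate_trial(s[1, ], 1, 1, cfg0)
  b <- generate_trial(s[1, ], 1, 1, cfg0)
  expect_identical(a, b)
  disp <- a$positions[nrow(a$positions), "x"] - a$positions[1, "x"]
  expect_equal(unname(disp), s$reach_amplitude[1], tolerance = 1e-9)
})

test_that("trial noise is small, smooth and nonzero at default settings", {
  s <- draw_subjects(1, 5)
  cfg <- synth_config(n_subjects = 1, seed = 5)
  r1 <- generate_trial(s[1, ], 1, 1, cfg)
  r2 <- generate_trial(s[1, ], 1, 2, cfg)
  d <- mean(sqrt(rowSums((r1$positions - r2$positions)^2)))
  expect_gt(d, 0)
  expect_lt(d, 0.05)
})

test_that("yaw crosses the wrap while gyro channels stay smooth", {
  # constructed case with the boundary just below the start yaw
  params <- list(subject_id = "S01", reach_amplitude = 0.9,
                 movement_duration = 1.4, peak_fraction = 0.5,
                 wrist_sweep_angle = 2.44,
                 axis_x = 0.1 / sqrt(1.0825), axis_y = 1 / sqrt(1.0825),
                 axis_z = 0.28 / sqrt(1.0825),
                 lateral_curvature = 0, base_yaw = pi - 0.05)
  cfg0 <- synth_config(n_subjects = 1, trial_noise_pos = 0,
                       trial_noise_angle = 0, day_drift_scale = 0, seed = 1)
  rec <- generate_trial(params, 1, 1, cfg0)
  e <- quat_to_euler(enforce_quat_continuity(rec$orientations))
  expect_gt(max(abs(diff(e[, "yaw"]))), pi)
  ks <- transform_recording(rec)
  expect_lt(max(abs(diff(ks$angular_velocity))), 1)
  # drawn subjects under default noise show the same contrast
  s <- draw_subjects(4, 31)
  cfg <- synth_config(n_subjects = 4, seed = 31)
  for (i in 1:4) {
    rec <- generate_trial(s[i, ], 2, 1, cfg)
    e <- quat_to_euler(enforce_quat_continuity(rec$orientations))
    expect_gt(max(abs(diff(e[, "yaw"]))), pi)
    ks <- transform_recording(rec)
    expect_lt(max(abs(diff(ks$angular_velocity))), 1)
  }
})

test_that("generated datasets have the right shape and reproduce from seed", {
  man <- local_dataset(n_subjects = 3, trials = 2, seed = 5)
  expect_equal(nrow(man), 3 * 2 * 2)
  key <- paste(man$subject_id, man$day, man$trial, man$device)
  expect_equal(anyDuplicated(key), 0L)
  # default 45 Hz x 3 s recordings are 135 frames long
  rec <- read_pose_csv(file.path(attr(man, "base_dir"), man$path[1]))
  expect_equal(length(rec), 135)
  expect_equal(rec$sample_rate, 45, tolerance = 1e-6)
  expect_lt(max(abs(sqrt(rowSums(rec$orientations^2)) - 1)), 1e-6)
  # regenerating with the same config is bitwise identical
  cfg <- synth_config(n_subjects = 2, trials_per_day = 1, n_days = 1,
                      seed = 5)
  d1 <- file.path(tempdir(), "regen1")
  d2 <- file.path(tempdir(), "regen2")
  m1 <- generate_dataset(cfg, d1)
  m2 <- generate_dataset(cfg, d2)
  expect_equal(m1$path, m2$path)
  for (p in m1$path) {
    expect_identical(readLines(file.path(d1, p)),
                     readLines(file.path(d2, p)))
  }
})

test_that("a 41 x 10 x 2 configuration lists 820 recordings", {
  cfg <- synth_config(n_subjects = 41, trials_per_day = 10, n_days = 2,
                      sample_rate = 45, duration = 1, seed = 2)
  # duration shortened: the count depends only on the index structure
  man <- generate_dataset(cfg, file.path(tempdir(), "full-count"))
  expect_equal(nrow(man), 820)
})

test_that("between-subject variation exceeds within-subject trial noise", {
  man <- local_dataset(n_subjects = 6, trials = 4, seed = 19)
  base <- attr(man, "base_dir")
  # summary feature: total displacement and peak body-frame speed
  feat <- t(vapply(seq_len(nrow(man)), function(i) {
    rec <- read_pose_csv(file.path(base, man$path[i]))
    v <- body_velocity(rec)
    c(disp = sum(abs(rec$positions[nrow(rec$positions), ] -
                     rec$positions[1, ])),
      speed = max(sqrt(rowSums(v^2))))
  }, numeric(2)))
  for (j in 1:2) {
    mu <- tapply(feat[, j], man$subject_id, mean)
    within <- tapply(feat[, j], man$subject_id, stats::var)
    expect_gt(stats::var(mu), mean(within))
  }
})

test_that("day drift makes cross-day matching harder than same-day", {
  # nearest-neighbour classifier on resampled gyro features; averaged
  # over seeds the cross-day accuracy must not beat same-day accuracy
  acc <- function(train_idx, test_idx, feat, labels) {
    d <- as.matrix(stats::dist(feat))
    pred <- labels[train_idx][apply(d[test_idx, train_idx, drop = FALSE],
                                    1L, which.min)]
    mean(pred == labels[test_idx])
  }
  same <- cross <- numeric(3)
  for (k in 1:3) {
    man <- local_dataset(n_subjects = 5, trials = 4, seed = 100 + k)
    base <- attr(man, "base_dir")
    feat <- t(vapply(seq_len(nrow(man)), function(i) {
      rec <- read_pose_csv(file.path(base, man$path[i]))
      ks <- transform_recording(rec, cutoff = 6)
      as.vector(resample_channels(ks$angular_velocity, 24))
    }, numeric(72)))
    labels <- man$subject_id
    d1 <- which(man$day == 1)
    odd <- d1[man$trial[d1] %% 2 == 1]
    even <- d1[man$trial[d1] %% 2 == 0]
    same[k] <- acc(odd, even, feat, labels)
    cross[k] <- acc(which(man$day == 1), which(man$day == 2), feat, labels)
  }
  expect_lte(mean(cross), mean(same))
})
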