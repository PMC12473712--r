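test_that("sign-continuity enforcement heals injected flips exactly", {
  q <- random_unit_quat(1)
  qq <- q[rep(1, 3), ]
  expect_equal(enforce_quat_continuity(qq), qq, ignore_attr = TRUE)
  expect_equal(enforce_quat_continuity(rbind(q, -q)), rbind(q, q),
               ignore_attr = TRUE)
  smooth <- smooth_quat_sequence(200, seed = 9)
  set.seed(10)
  flips <- sample(2:200, 5)
  broken <- smooth
  for (f in flips) broken[f:200, ] <- -broken[f:200, ]
  expect_equal(enforce_quat_continuity(broken), smooth, ignore_attr = TRUE)
})

test_that("quaternion forward difference matches direct arithmetic", {
  n <- 50
  q <- const_orient(random_unit_quat(4), n)
  expect_equal(quat_derivative(q, 0.02), matrix(0, n, 4),
               ignore_attr = TRUE)
  d <- quat_derivative(rbind(c(1, 0, 0, 0), c(0.9, 0.1, 0, 0)), 0.1)
  expect_equal(unname(d[1, ]), c(-1, 1, 0, 0))
  expect_equal(d[2, ], d[1, ])  # end padding duplicates the last difference
  expect_error(quat_derivative(quat(1, 0, 0, 0), 0.1), "2 samples")
})

test_that("constant-rate rotation recovers its angular rate", {
  rate <- 2.5  # rad/s about +Z
  t <- seq(0, 3, by = 1 / 60)
  q <- vrimu:::quat_from_axis_angle(c(0, 0, 1), rate * t)
  dq <- quat_derivative(q, 1 / 60)
  om <- 2 * quat_product(quat_conjugate(q), dq)[, 2:4]
  interior <- 1:(length(t) - 1)
  expect_lt(max(abs(om[interior, 3] - rate)) / rate, 0.005)
  expect_lt(max(abs(om[interior, 1:2])), 0.01)
})

test_that("body velocity rotates world motion into the sensor frame", {
  n <- 60
  rec <- pose_recording(matrix(1.5, n, 3), identity_orient(n), 60)
  expect_equal(unname(body_velocity(rec)), matrix(0, n, 3))
  # constant world velocity (1,0,0) seen from a 90-degree-yawed body
  t <- (seq_len(n) - 1) / 60
  rec2 <- pose_recording(cbind(t, 0, 0),
                         const_orient(c(sqrt(0.5), 0, 0, sqrt(0.5)), n), 60)
  v <- body_velocity(rec2)
  expect_equal(unname(v), matrix(rep(c(0, -1, 0), each = n), n),
               tolerance = 1e-9)
  # speed is frame independent
  rec3 <- random_recording(21)
  pdot <- vrimu:::forward_diff(rec3$positions, 1 / rec3$sample_rate)
  expect_lt(max(abs(sqrt(rowSums(body_velocity(rec3)^2)) -
                    sqrt(rowSums(pdot^2)))), 1e-10)
})

test_that("body acceleration is exact for quadratic and affine paths", {
  t <- seq(0, 2, by = 1 / 60)
  n <- length(t)
  # uniform acceleration along X: p = g t^2 / 2
  rec <- pose_recording(cbind(0.5 * 9.81 * t^2, 0, 0),
                        identity_orient(n), 60)
  a <- body_acceleration(rec)
  interior <- 1:(n - 2)  # double forward difference pads the last two
  expect_lt(max(abs(a[interior, 1] - 9.81)) / 9.81, 1e-6)
  # affine trajectories have identically zero interior acceleration
  rec2 <- pose_recording(cbind(1 + 2 * t, 3 - t, 0.5 * t),
                         identity_orient(n), 60)
  expect_lt(max(abs(body_acceleration(rec2)[interior, ])), 1e-9)
})

test_that("circular motion recovers the centripetal magnitude", {
  t <- seq(0, 2, by = 1 / 60)
  n <- length(t)
  rec <- pose_recording(cbind(0.5 * cos(2 * pi * t), 0.5 * sin(2 * pi * t), 0),
                        identity_orient(n), 60)
  mag <- sqrt(rowSums(body_acceleration(rec)^2))
  target <- 0.5 * (2 * pi)^2  # 19.74 m/s^2
  expect_lt(max(abs(mag[3:(n - 3)] - target)) / target, 0.01)
})

test_that("gravity flag yields specific force for a resting sensor", {
  n <- 30
  rec <- pose_recording(matrix(0, n, 3), identity_orient(n), 60)
  a <- body_acceleration(rec, add_gravity = TRUE)
  expect_equal(unname(a), matrix(rep(c(0, 0, 9.81), each = n), n),
               tolerance = 1e-12)
  # default leaves gravity out entirely
  expect_equal(unname(body_acceleration(rec)), matrix(0, n, 3))
})

test_that("angular velocity agrees with the conjugate-product oracle", {
  n <- 100
  expect_equal(unname(angular_velocity(const_orient(random_unit_quat(5), n),
                                       1 / 60)),
               matrix(0, n, 3))
  worst <- 0
  for (seed in 1:100) {
    q <- smooth_quat_sequence(40, seed = 1000 + seed)
    dq <- quat_derivative(q, 1 / 60)
    oracle <- 2 * quat_product(quat_conjugate(q), dq)[, 2:4]
    worst <- max(worst, max(abs(angular_velocity(q, 1 / 60) - oracle)))
  }
  expect_lt(worst, 1e-12)
  expect_error(angular_velocity(quat(2, 0, 0, 0)[rep(1, 5), ], 0.1),
               "non-unit")
})

test_that("rotation about +Z at pi rad/s is recovered within tolerance", {
  t <- seq(0, 3, by = 1 / 60)
  q <- vrimu:::quat_from_axis_angle(c(0, 0, 1), pi * t)
  om <- angular_velocity(q, 1 / 60)
  m <- colMeans(om[1:(length(t) - 1), ])
  expect_lt(max(abs(m - c(0, 0, pi))), 0.02)
})

test_that("angular-velocity error shrinks at least linearly with dt", {
  errs <- vapply(c(30, 60, 120), function(fs) {
    t <- seq(0, 2, by = 1 / fs)
    q <- vrimu:::quat_from_axis_angle(c(0, 0, 1), 2 * t)
    om <- angular_velocity(q, 1 / fs)
    max(abs(om[1:(length(t) - 1), 3] - 2))
  }, numeric(1))
  expect_lt(errs[2] / errs[1], 0.6)  # halving dt at least halves the error
  expect_lt(errs[3] / errs[2], 0.6)
})

test_that("zero-phase Butterworth has unit DC gain and the expected roll-off", {
  expect_lt(max(abs(lowpass_filter(rep(5, 600), 3, 60) - 5)), 1e-9)
  t <- seq(0, 10, by = 1 / 60)
  mid <- 150:450  # central half, away from edge effects
  at_cut <- max(abs(lowpass_filter(sin(2 * pi * 3 * t), 3, 60)[mid]))
  expect_lt(abs(at_cut - 0.5), 0.025)  # two passes of -3 dB
  stop_band <- max(abs(lowpass_filter(sin(2 * pi * 20 * t), 3, 60)[mid]))
  expect_lt(stop_band, 0.01)
  expect_error(lowpass_filter(rnorm(100), 30, 60), "Nyquist")
})

test_that("full transform is zero for a stationary identity recording", {
  n <- 64
  rec <- pose_recording(matrix(2, n, 3), identity_orient(n), 45)
  ks <- transform_recording(rec)
  expect_equal(unname(ks$velocity), matrix(0, n, 3))
  expect_equal(unname(ks$acceleration), matrix(0, n, 3))
  expect_equal(unname(ks$angular_velocity), matrix(0, n, 3))
})

test_that("low-pass conditioning strictly reduces channel variance", {
  subj <- draw_subjects(1, 3)
  rec <- generate_trial(subj[1, ], 1, 1, synth_config(n_subjects = 1, seed = 3))
  raw <- transform_recording(rec)
  filt <- transform_recording(rec, cutoff = 3)
  for (j in 1:3) {
    expect_lt(stats::var(filt$acceleration[, j]),
              stats::var(raw$acceleration[, j]))
  }
})

test_that("body-frame outputs are invariant to world-frame re-orientation", {
  worst <- 0
  for (seed in 1:100) {
    rec <- random_recording(seed, n = 60)
    r <- random_unit_quat(seed + 5000)
    pos_rot <- rotate_body_to_world(r, rec$positions)  # world vectors by r
    rec_rot <- pose_recording(pos_rot,
                              quat_product(r, rec$orientations),
                              rec$sample_rate)
    a <- transform_recording(rec)
    b <- transform_recording(rec_rot)
    worst <- max(worst,
                 max(abs(a$velocity - b$velocity)),
                 max(abs(a$acceleration - b$acceleration)),
                 max(abs(a$angular_velocity - b$angular_velocity)))
  }
  expect_lt(worst, 1e-9)
})
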