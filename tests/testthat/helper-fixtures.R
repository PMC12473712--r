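# Shared fixtures, built in code at test time.

# smooth random unit-quaternion sequence: random slowly varying rotation
# vector integrated over time
smooth_quat_sequence <- function(n, seed, rate = 60) {
  set.seed(seed)
  omega <- matrix(rnorm(3 * n, sd = 2), n, 3)
  for (j in 1:3) omega[, j] <- stats::filter(omega[, j], rep(1 / 15, 15),
                                             sides = 1)
  omega[is.na(omega)] <- 0
  q <- matrix(0, n, 4)
  q[1, ] <- c(1, 0, 0, 0)
  dt <- 1 / rate
  for (i in 2:n) {
    dq <- vrimu:::rotvec_to_quat(matrix(omega[i, ] * dt, 1))
    q[i, ] <- quat_product(q[i - 1, , drop = FALSE], dq)
  }
  quat_normalize(q)
}

random_unit_quat <- function(seed) {
  set.seed(seed)
  quat_normalize(matrix(rnorm(4), 1))
}

# seeded random pose recording with smooth positions and orientations
random_recording <- function(seed, n = 120, rate = 60) {
  set.seed(seed)
  t <- (seq_len(n) - 1) / rate
  pos <- cbind(
    cumsum(cumsum(rnorm(n, sd = 1e-3))) + 0.5 * t,
    sin(2 * pi * 0.7 * t) * 0.3,
    cos(2 * pi * 0.4 * t) * 0.2
  )
  pose_recording(pos, smooth_quat_sequence(n, seed + 1, rate), rate)
}

const_orient <- function(q, n) as_quat(q)[rep(1L, n), , drop = FALSE]

identity_orient <- function(n) const_orient(c(1, 0, 0, 0), n)

# rotation matrix from axis-angle, used as an oracle independent of the
# quaternion implementation (Rodrigues formula)
rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# tiny on-disk synthetic dataset, cached per test session
local_dataset <- local({
  cache <- new.env(parent = emptyenv())
  function(n_subjects = 3, trials = 2, seed = 5, ...) {
    key <- paste(n_subjects, trials, seed, ...)
    if (is.null(cache[[key]])) {
      cfg <- synth_config(n_subjects = n_subjects, trials_per_day = trials,
                          seed = seed, ...)
      dir <- file.path(tempdir(), paste0("vrimu-ds-", abs(digest_key(key))))
      cache[[key]] <- generate_dataset(cfg, dir)
    }
    cache[[key]]
  }
})

digest_key <- function(s) sum(utf8ToInt(s) * seq_len(nchar(s)))
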