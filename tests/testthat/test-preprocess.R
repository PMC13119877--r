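# Preprocessing chain: keypoint normalization, zero-phase Butterworth
# filtering, Z-scores, spline resampling and windowing.

test_that("keypoint normalization centres, scales and is scale invariant", {
  # two joints at (1,1), (3,3): centroid (2,2), Euclidean reference length
  # sqrt(8), so normalized coordinates are +-1/sqrt(8) per axis
  fr <- array(c(1, 3, 1, 3), dim = c(1, 2, 2))
  out <- normalize_keypoints(fr, "shoulder_width")
  expect_equal(out[1, , ], matrix(c(-1, 1, -1, 1) / sqrt(8), 2, 2),
               tolerance = 1e-12)
  # scale invariance: any c > 0 gives identical output
  out5 <- normalize_keypoints(fr * 5, "shoulder_width")
  expect_equal(out5[1, , ], out[1, , ], tolerance = 1e-12)
  # per-frame centroid of valid joints is ~0
  set.seed(1)
  fr2 <- array(rnorm(10 * 17 * 2), dim = c(10, 17, 2))
  o2 <- normalize_keypoints(fr2, "torso_length")
  for (t in 1:10) expect_lt(max(abs(colMeans(o2[t, , ]))), 1e-12)
})

test_that("degenerate poses are flagged invalid, not divided", {
  fr <- array(1, dim = c(1, 5, 2))   # all joints at one point
  out <- normalize_keypoints(fr, "shoulder_width")
  expect_false(any(attr(out, "mask")))
  expect_true(all(out == 0))
})

test_that("normalization is idempotent given the induced scale", {
  set.seed(2)
  fr <- array(rnorm(5 * 17 * 2, sd = 2), dim = c(5, 17, 2))
  once <- normalize_keypoints(fr, "torso_length")
  twice <- normalize_keypoints(once, "torso_length")
  expect_equal(twice[, , ], once[, , ], tolerance = 1e-9)
})

test_that("Butterworth band-pass removes DC and passes in-band tones at unit gain", {
  cfg <- preprocess_config(grid_rate = 1000)
  # constant channel -> essentially zero after band-passing
  dc <- matrix(3, 2000, 1)
  out <- filter_standardize(dc, 1000, cfg, "emg", standardize = FALSE)
  expect_lt(max(abs(out)), 1e-6 * 3)
  # 100 Hz unit sinusoid, band (20, 450) order 4: amplitude within 1% of 1
  # (amplitude estimated by projection onto the sin/cos pair, the analytic
  # magnitude-response oracle; a sampled peak would understate it)
  t <- (0:3999) / 1000
  x <- matrix(sin(2 * pi * 100 * t), ncol = 1)
  y <- filter_standardize(x, 1000, cfg, "emg", standardize = FALSE)
  inner <- 500:3500
  amp <- sqrt((2 * mean(y[inner] * sin(2 * pi * 100 * t[inner])))^2 +
                (2 * mean(y[inner] * cos(2 * pi * 100 * t[inner])))^2)
  expect_lt(abs(amp - 1), 0.01)
  # zero-phase: cross-correlation peak of the in-band tone at lag 0
  ccf_vals <- sapply(-5:5, function(L) {
    i <- 1000:3000
    stats::cor(x[i], y[i - L])
  })
  expect_equal((-5:5)[which.max(ccf_vals)], 0)
  # band edges at or above Nyquist are rejected
  expect_error(filter_standardize(x, 400, cfg, "emg"), "Nyquist")
})

test_that("Z-score standardization is exact and respects frozen statistics", {
  set.seed(3)
  x <- matrix(rnorm(500 * 3, mean = 4, sd = 2), 500, 3)
  cfg <- preprocess_config(grid_rate = 100)
  z <- filter_standardize(x, 100, cfg, "imu")
  expect_lt(max(abs(colMeans(z))), 1e-9)
  expect_true(all(abs(apply(z, 2, sd) - 1) < 1e-6))
  stats_frozen <- list(mean = c(1, 2, 3), sd = c(1, 1, 2))
  z2 <- filter_standardize(x, 100, cfg, "imu", stats = stats_frozen)
  expect_equal(z2, sweep(sweep(x, 2, c(1, 2, 3)), 2, c(1, 1, 2), "/"),
               tolerance = 1e-12)
})

test_that("spline resampling reproduces cubics and exact source samples", {
  t <- (0:29) / 30
  x <- matrix(2 - t + 3 * t^2 - 0.5 * t^3, ncol = 1)
  up <- resample_to_grid(x, 30, 240)
  tg <- attr(up, "times")
  truth <- 2 - tg + 3 * tg^2 - 0.5 * tg^3
  expect_lt(max(abs(up - truth) / max(abs(truth))), 1e-9)
  # grid points coinciding with source samples are exactly reproduced
  up2 <- resample_to_grid(x, 30, 60)
  expect_equal(up2[seq(1, nrow(up2), by = 2)], x[1:ceiling(nrow(up2) / 2)],
               tolerance = 1e-12)
  # no extrapolation: grid never extends past the last source sample
  expect_lte(max(attr(up, "times")), (nrow(x) - 1) / 30)
  # 1 Hz sinusoid sampled at 30 Hz, upsampled to 1000 Hz
  t2 <- (0:119) / 30
  s <- matrix(sin(2 * pi * t2), ncol = 1)
  up3 <- resample_to_grid(s, 30, 1000)
  tg3 <- attr(up3, "times")
  interior <- tg3 > 0.2 & tg3 < max(tg3) - 0.2
  expect_lt(max(abs(up3[interior] - sin(2 * pi * tg3[interior]))), 1e-4)
  expect_error(resample_to_grid(s, 30, -5), "positive")
})

test_that("round trip: source timestamps recover the source exactly", {
  set.seed(4)
  x <- matrix(rnorm(40), ncol = 2)
  up <- resample_to_grid(x, 20, 200)
  back <- up[seq(1, nrow(up), by = 10), ]
  expect_equal(back, x[seq_len(nrow(back)), ], tolerance = 1e-12)
})

test_that("windowing arithmetic and phase-label mapping are exact", {
  # a hair over 10 s so the unified grid (which never extrapolates past the
  # last 30 Hz skeleton sample) still covers a full 10 s of windows
  cfg <- generator_config(seed = 13, trial_duration = 10.2)
  s <- synthesize_trial(cfg, "S001", 4, seed = 2)
  pp <- preprocess_config(grid_rate = 100, window_seconds = 4,
                          window_stride_seconds = 2)
  wins <- preprocess_session(s, pp)
  expect_length(wins, 4)   # 10 s trial, 4 s window, 2 s stride
  expect_true(all(vapply(wins, function(w) nrow(w$imu) == 400, logical(1))))
  # stride = window: non-overlapping, sample counts conserved
  pp2 <- preprocess_config(grid_rate = 100, window_seconds = 2,
                           window_stride_seconds = 2)
  wins2 <- preprocess_session(s, pp2)
  expect_length(wins2, 5)  # five non-overlapping 2 s windows fit in 10.2 s
  starts <- vapply(wins2, `[[`, numeric(1), "start_time")
  expect_equal(diff(starts), rep(2, length(starts) - 1))
  # phase boundaries move to the nearest grid tick: displacement <= half a
  # 30 Hz source frame
  grid_phase <- wins2[[1]]$phase
  src_phase <- s$phase_labels
  t_g <- (seq_along(grid_phase) - 1) / 100
  for (i in which(diff(grid_phase) != 0)[1:3]) {
    b_grid <- t_g[i + 1]
    src_switch <- which(diff(src_phase) != 0) + 1
    b_src <- (src_switch - 1) / 30
    expect_lte(min(abs(b_src - b_grid)), 0.5 / 30 + 1e-9)
  }
  # too-short session: zero windows with a warning
  pp3 <- preprocess_config(grid_rate = 100, window_seconds = 20,
                           window_stride_seconds = 20)
  expect_warning(w0 <- preprocess_session(s, pp3), "shorter")
  expect_length(w0, 0)
})

test_that("whole-dataset preprocessing freezes training statistics", {
  ds <- generate_dataset(generator_config(n_subjects = 10, n_classes = 2,
                                          trial_duration = 4, seed = 3))
  pp <- preprocess_config(grid_rate = 24, window_seconds = 2,
                          window_stride_seconds = 2)
  dat <- build_windows(ds, pp)
  expect_equal(length(dat$windows), length(dat$split))
  expect_setequal(unique(dat$split), c("train", "val", "test"))
  expect_named(dat$stats, c("imu", "emg"))
  # grid length: 2 s at 24 Hz
  expect_true(all(vapply(dat$windows, function(w) nrow(w$imu) == 48, logical(1))))
})
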