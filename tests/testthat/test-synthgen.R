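# Synthetic multimodal generator: determinism, cross-modal consistency,
# offset identifiability, balanced subject-independent datasets, and the
# quantified perturbations.

test_that("trials are deterministic and dimensioned by the acquisition rates", {
  cfg <- generator_config(seed = 7)
  s1 <- synthesize_trial(cfg, "S001", 3, seed = 42)
  s2 <- synthesize_trial(cfg, "S001", 3, seed = 42)
  expect_identical(s1, s2)
  expect_equal(nrow(s1$skeleton), round(cfg$trial_duration * 30))
  expect_equal(nrow(s1$imu), round(cfg$trial_duration * 100))
  expect_equal(nrow(s1$emg), round(cfg$trial_duration * 1000))
  expect_equal(dim(s1$skeleton)[2:3], c(17, 2))
  expect_equal(length(s1$phase_labels), nrow(s1$skeleton))
  expect_true(all(s1$phase_labels %in% 1:4))
  expect_gte(s1$stability_true, 0)
  expect_lte(s1$stability_true, 1)
  expect_true(all(abs(s1$offsets_true) <= cfg$offset_range))
  s3 <- synthesize_trial(cfg, "S001", 3, seed = 43)
  expect_false(identical(s1$skeleton, s3$skeleton))
  expect_error(synthesize_trial(cfg, "S001", 99, seed = 1), "unknown action class")
  expect_error(generator_config(trial_duration = -1), "positive")
  expect_error(generator_config(rates = c(skeleton = 0, imu = 100, emg = 1000)),
               "strictly positive")
})

test_that("noise-free IMU equals the discrete second derivative of its source joint", {
  cfg <- generator_config(seed = 7, offset_range = 0, emg_latency = 0,
                          noise_floor = c(skeleton = 0, imu = 0, emg = 0))
  s <- synthesize_trial(cfg, "S001", 3, seed = 42)
  rate <- s$rates[["imu"]]
  for (ch in which(s$imu_map$type %in% c("acc_x", "acc_y"))) {
    ji <- match(s$imu_map$joint[ch], s$kinematics$joints)
    ax <- if (s$imu_map$type[ch] == "acc_x") 1 else 2
    ref <- second_difference(s$kinematics$pos[, ji, ax], rate)
    obs <- s$imu[, ch] - if (s$imu_map$gravity[ch]) 9.81 else 0
    amp <- max(abs(ref))
    expect_lt(max(abs(obs - ref)), 1e-3 * amp)
  }
  # independent route: spline-upsample the 30 Hz skeleton and differentiate
  ch <- which(s$imu_map$type == "acc_x")[1]
  j <- s$imu_map$joint[ch]
  t_s <- (seq_len(nrow(s$skeleton)) - 1) / 30
  t_i <- (seq_len(nrow(s$imu)) - 1) / rate
  sf <- stats::splinefun(t_s, s$skeleton[, j, 1])
  ref2 <- second_difference(sf(t_i), rate)
  amp <- max(abs(ref2))
  inner <- 10:(length(ref2) - 10)
  # double-differencing amplifies the 30 Hz interpolation error, hence the
  # looser tolerance of this independent route
  expect_lt(max(abs(s$imu[inner, ch] - ref2[inner])), 0.1 * amp)
})

test_that("EMG envelope lag recovers the injected clock offset minus the neuromuscular lead", {
  cfg <- generator_config(seed = 7, offset_range = 0.08,
                          noise_floor = c(skeleton = 0, imu = 0, emg = 0),
                          emg_gain_sd = 0, emg_drift = 0)
  for (trial_seed in c(11, 23)) {
    s <- synthesize_trial(cfg, "S001", 5, seed = trial_seed)
    j <- s$emg_joints[1]
    te <- (seq_len(nrow(s$emg)) - 1) / 1000
    ts <- (seq_len(nrow(s$skeleton)) - 1) / 30
    # brute-force oracle: spline the skeleton joint, differentiate to speed,
    # scan every lag for the cross-correlation maximum with |EMG| envelope
    vx <- stats::splinefun(ts, s$skeleton[, j, 1])(te, deriv = 1)
    vy <- stats::splinefun(ts, s$skeleton[, j, 2])(te, deriv = 1)
    spd <- sqrt(vx^2 + vy^2)
    lp <- signal::butter(2, 5 / 500, "low")
    env <- zero_phase_filter(lp, abs(s$emg[, 1]))
    n <- length(env)
    lags <- -150:150
    cc <- vapply(lags, function(L) {
      i1 <- max(1, 1 + L):min(n, n + L)
      stats::cor(env[i1], spd[i1 - L])
    }, numeric(1))
    best <- lags[which.max(cc)] / 1000
    expected <- s$offsets_true[["emg"]] - cfg$emg_latency
    expect_lt(abs(best - expected), 1.5e-3)  # within a 1000 Hz sample + filter slack
  }
})

test_that("datasets are class-balanced with a disjoint 70/10/20 subject split", {
  cfg <- generator_config(n_subjects = 10, trials_per_subject = 2,
                          trial_duration = 4, n_classes = 4, seed = 5)
  ds <- generate_dataset(cfg)
  man <- ds$manifest
  expect_equal(nrow(man), 10 * 2 * 4)
  expect_true(all(table(man$class) == 10 * 2))
  sp <- split(man$subject_id, man$split)
  expect_equal(length(unique(sp$train)), 7)
  expect_equal(length(unique(sp$val)), 1)
  expect_equal(length(unique(sp$test)), 2)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_length(intersect(sp$val, sp$test), 0)
  # seed isolation: different seed, different assignment, same proportions
  ds2 <- generate_dataset(generator_config(n_subjects = 10, trials_per_subject = 2,
                                           trial_duration = 4, n_classes = 4,
                                           seed = 6))
  sp2 <- split(ds2$manifest$subject_id, ds2$manifest$split)
  expect_equal(lengths(sp2)[order(names(sp2))], lengths(sp)[order(names(sp))])
  expect_false(identical(sort(unique(sp$test)), sort(unique(sp2$test))))
  expect_error(generate_dataset(generator_config(n_subjects = 5, n_classes = 2,
                                                 trial_duration = 4)),
               ">= 10 subjects")
})

test_that("skeleton spectral features separate classes for a 1-NN classifier", {
  cfg <- generator_config(n_subjects = 10, trials_per_subject = 1,
                          trial_duration = 4, seed = 31)
  ds <- generate_dataset(cfg)
  feats <- t(vapply(ds$sessions, function(s) {
    sp <- abs(stats::mvfft(s$skeleton[, 10, ]))[2:20, ]
    as.numeric(sp)
  }, numeric(38)))
  labs <- ds$manifest$class
  pred <- vapply(seq_len(nrow(feats)), function(i) {
    d <- colSums((t(feats[-i, ]) - feats[i, ])^2)
    labs[-i][which.min(d)]
  }, numeric(1))
  expect_gt(mean(pred == labs), 0.8)
})

test_that("perturbations act as specified and never alter labels", {
  cfg <- generator_config(seed = 9, trial_duration = 4)
  s <- synthesize_trial(cfg, "S001", 2, seed = 1)

  expect_identical(perturb(s, perturbation_spec("none")), s)

  # occlusion: round(0.5 * 17) joints zeroed per frame
  occ <- perturb(s, perturbation_spec("occlusion", occlusion_fraction = 0.5),
                 seed = 3)
  masked_per_frame <- rowSums(!occ$masks$skeleton)
  expect_true(all(masked_per_frame == round(0.5 * 17)))
  expect_true(all(occ$skeleton[!occ$masks$skeleton] == 0))
  expect_identical(occ$phase_labels, s$phase_labels)
  expect_identical(occ$action_class, s$action_class)

  # empirical SNR of injected sensor noise within +-0.5 dB (a long trial
  # keeps the per-channel noise-power estimate tight)
  s10 <- synthesize_trial(generator_config(seed = 9, trial_duration = 10),
                          "S001", 2, seed = 1)
  nz <- perturb(s10, perturbation_spec("sensor_noise", snr_db = 20), seed = 4)
  for (mod in c("imu", "emg")) {
    snr_emp <- 10 * log10(colMeans(s10[[mod]]^2) /
                            colMeans((nz[[mod]] - s10[[mod]])^2))
    expect_true(all(abs(snr_emp - 20) < 0.5))
  }

  # viewpoint rotation preserves pairwise distances within each frame
  vp <- perturb(s, perturbation_spec("viewpoint", rotation_deg = 15), seed = 5)
  d0 <- dist(s$skeleton[1, , ])
  d1 <- dist(vp$skeleton[1, , ])
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-10)
  expect_false(isTRUE(all.equal(vp$skeleton, s$skeleton)))

  # modality loss: zeros + cleared validity for the whole trial
  ml <- perturb(s, perturbation_spec("modality_loss", lost_modality = "emg"),
                seed = 6)
  expect_true(all(ml$emg == 0))
  expect_false(any(ml$masks$emg))
  expect_error(perturbation_spec("occlusion", occlusion_fraction = 1.4),
               "\\[0, 1\\]")
})

test_that("session round-trips through the plain-text container", {
  cfg <- generator_config(seed = 9, trial_duration = 4)
  s <- synthesize_trial(cfg, "S001", 2, seed = 1)
  s$session_id <- "roundtrip"
  dir <- file.path(tempdir(), "mf_session")
  write_session(s, dir)
  s2 <- read_session(dir)
  expect_equal(s2$skeleton, s$skeleton, tolerance = 1e-12)
  expect_equal(s2$imu, s$imu, tolerance = 1e-12)
  expect_equal(s2$offsets_true, s$offsets_true)
  expect_equal(s2$action_class, s$action_class)
  expect_equal(s2$phase_labels, s$phase_labels)
  unlink(dir, recursive = TRUE)
})
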