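# Synthetic multimodal session generator.
#
# Emulates a three-stream acquisition rig: 2-D skeleton keypoints from video
# pose estimation (30 Hz), limb-mounted IMUs (100 Hz) and surface EMG
# (1000 Hz). All three streams are driven by one analytic, per-trial
# kinematic model (sums of sinusoidal joint motifs), so cross-modal
# consistency (IMU = second derivative of limb trajectories, EMG envelope =
# neuromuscular-lead copy of limb speed) holds by construction and the
# injected inter-modality clock offsets are exactly known.

# Reference standing pose, COCO-17 joint order, metres, y up.
.coco17_base <- function() {
  m <- rbind(
    c(0.00, 1.70),  c(-0.05, 1.75), c(0.05, 1.75), c(-0.10, 1.72), c(0.10, 1.72),
    c(-0.20, 1.50), c(0.20, 1.50),  c(-0.30, 1.25), c(0.30, 1.25),
    c(-0.35, 1.00), c(0.35, 1.00),  c(-0.12, 1.00), c(0.12, 1.00),
    c(-0.14, 0.55), c(0.14, 0.55),  c(-0.15, 0.10), c(0.15, 0.10))
  colnames(m) <- c("x", "y")
  m
}

.base_pose <- function(J) {
  b <- .coco17_base()
  if (J <= 17L) return(b[seq_len(J), , drop = FALSE])
  extra <- cbind(seq(-0.3, 0.3, length.out = J - 17L), rep(0.8, J - 17L))
  rbind(b, extra)
}

# Limb joints used as IMU/EMG attachment sites (wrists, ankles, hips,
# elbows, knees), recycled as needed.
.limb_sites <- function(J) {
  s <- c(10L, 17L, 12L, 11L, 16L, 13L, 8L, 15L, 9L, 14L)
  s <- s[s <= J]
  if (length(s) == 0L) s <- seq_len(J)
  s
}

#' Configuration for the synthetic multimodal generator
#'
#' Holds the acquisition constants of the emulated rig (sampling rates,
#' channel counts, 12 action classes) together with the generator's own
#' knobs: the range of the per-modality clock offset, the neuromuscular lead
#' of the EMG envelope relative to the kinematics, per-stream measurement
#' noise and the postural-jitter bound that defines the ground-truth
#' stability score.
#'
#' @param n_subjects Number of subjects.
#' @param trials_per_subject Repetitions of *each* action class performed by
#'   every subject (so every subject contributes
#'   `n_classes * trials_per_subject` trials and the class histogram is
#'   uniform by construction).
#' @param n_classes Number of action classes (>= 2).
#' @param n_joints Number of 2-D skeleton keypoints J.
#' @param imu_channels,emg_channels Channel counts of the wearable streams.
#' @param rates Named Hz triple `c(skeleton=, imu=, emg=)`.
#' @param trial_duration Trial length in seconds.
#' @param offset_range Bound (seconds) of the uniform per-modality clock
#'   offset; each trial draws one offset per sensor modality in
#'   `[-offset_range, offset_range]`.
#' @param emg_latency Seconds by which the EMG activation envelope *leads*
#'   the kinematic motif (electromechanical delay).
#' @param noise_floor Named per-modality measurement-noise standard
#'   deviations.
#' @param jitter_max Maximum postural-jitter amplitude; the ground-truth
#'   stability score is `1 - jitter/jitter_max`.
#' @param emg_gain_sd Log-sd of the per-channel, per-trial multiplicative
#'   EMG gain (surface EMG amplitude varies strongly with electrode
#'   placement and skin impedance between sessions).
#' @param emg_drift Amplitude of the slow (0.1-0.4 Hz) baseline drift of the
#'   EMG activation envelope, relative to the RMS source-joint speed.
#' @param phase_count Number of contiguous motion phases per motif cycle.
#' @param seed Integer seed; fully determines every generated byte.
#' @param offset_mode `"uniform"` draws each clock offset uniformly in
#'   `[-offset_range, offset_range]`; `"fixed"` injects an offset of exactly
#'   `offset_range` magnitude with random sign (controlled misalignment
#'   experiments).
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_subjects = 10L, trials_per_subject = 1L,
                             n_classes = 12L, n_joints = 17L,
                             imu_channels = 9L, emg_channels = 8L,
                             rates = c(skeleton = 30, imu = 100, emg = 1000),
                             trial_duration = 6, offset_range = 0.08,
                             emg_latency = 0.04,
                             noise_floor = c(skeleton = 0.005, imu = 0.05, emg = 0.02),
                             jitter_max = 0.15, emg_gain_sd = 0.4,
                             emg_drift = 0.4, phase_count = 4L, seed = 1L,
                             offset_mode = c("uniform", "fixed")) {
  offset_mode <- match.arg(offset_mode)
  stopif(any(rates <= 0), "all sampling rates must be strictly positive")
  stopif(offset_range < 0, "offset_range must be >= 0")
  stopif(n_classes < 2, "n_classes must be >= 2")
  stopif(trial_duration <= 0, "trial_duration must be positive")
  stopif(n_subjects < 1 || trials_per_subject < 1, "need at least one subject and trial")
  rates <- c(skeleton = unname(rates[["skeleton"]]), imu = unname(rates[["imu"]]),
             emg = unname(rates[["emg"]]))
  cfg <- list(n_subjects = as.integer(n_subjects),
              trials_per_subject = as.integer(trials_per_subject),
              n_classes = as.integer(n_classes), n_joints = as.integer(n_joints),
              imu_channels = as.integer(imu_channels),
              emg_channels = as.integer(emg_channels), rates = rates,
              trial_duration = trial_duration, offset_range = offset_range,
              emg_latency = emg_latency, noise_floor = noise_floor,
              jitter_max = jitter_max, emg_gain_sd = emg_gain_sd,
              emg_drift = emg_drift, phase_count = as.integer(phase_count),
              seed = as.integer(seed), offset_mode = offset_mode)
  class(cfg) <- "generator_config"
  cfg
}

# Class fundamental frequency: spread over [0.5, 2.5] Hz (gait/squat cadence
# band) so classes are separable in the motion spectrum.
class_frequency <- function(class, n_classes) {
  0.5 + 2.0 * (class - 1) / max(1, n_classes - 1)
}

# Per-class motif bank: for every joint a fundamental sinusoid plus one
# second-harmonic term, with class-specific amplitudes, directions and phase
# structure. The bank is a fixed codebook independent of the dataset seed.
.class_motif <- function(class, J) {
  with_seed(derive_seed(990017L, "motif", class, J), {
    limb <- .limb_sites(J)
    terms <- list()
    for (j in seq_len(J)) {
      amp <- stats::runif(1, 0.05, 0.25) * if (j %in% limb) 2 else 1
      th <- stats::runif(1, 0, 2 * pi)
      ph <- stats::runif(1, 0, 2 * pi)
      h_amp <- amp * stats::runif(1, 0.2, 0.5)
      th2 <- stats::runif(1, 0, 2 * pi)
      ph2 <- stats::runif(1, 0, 2 * pi)
      terms[[length(terms) + 1L]] <-
        c(j, 1, amp * cos(th), amp * sin(th), ph)
      terms[[length(terms) + 1L]] <-
        c(j, 2, h_amp * cos(th2), h_amp * sin(th2), ph2)
    }
    m <- do.call(rbind, terms)
    colnames(m) <- c("joint", "mult", "ax", "ay", "phase")
    m
  })
}

# Evaluate joint trajectories (or analytic time derivatives) of a trial
# model at arbitrary times. `model$terms` columns: joint, freq, ax, ay, phase.
eval_trajectory <- function(model, times, joints = NULL, deriv = 0L) {
  joints <- joints %||% seq_len(model$J)
  n <- length(times)
  out <- array(0, dim = c(n, length(joints), 2L))
  for (ji in seq_along(joints)) {
    j <- joints[ji]
    if (deriv == 0L) {
      out[, ji, 1] <- model$base[j, 1]
      out[, ji, 2] <- model$base[j, 2]
    }
    rows <- which(model$terms[, "joint"] == j)
    for (r in rows) {
      f <- model$terms[r, "freq"]
      w <- 2 * pi * f
      arg <- w * times + model$terms[r, "phase"]
      s <- switch(as.character(deriv),
                  "0" = sin(arg), "1" = w * cos(arg), "2" = -w^2 * sin(arg))
      out[, ji, 1] <- out[, ji, 1] + model$terms[r, "ax"] * s
      out[, ji, 2] <- out[, ji, 2] + model$terms[r, "ay"] * s
    }
  }
  out
}

# Build the analytic per-trial kinematic model: class motif + subject scale
# + postural jitter terms (low-amplitude 2.5-6 Hz sway). RNG state must be
# set by the caller.
.trial_model <- function(cfg, subject_scale, subject_shift, action_class, jitter_amp) {
  J <- cfg$n_joints
  f0 <- class_frequency(action_class, cfg$n_classes)
  motif <- .class_motif(action_class, J)
  terms <- cbind(joint = motif[, "joint"], freq = motif[, "mult"] * f0,
                 ax = motif[, "ax"] * subject_scale,
                 ay = motif[, "ay"] * subject_scale,
                 phase = motif[, "phase"])
  jt <- list()
  for (j in seq_len(J)) {
    for (k in 1:2) {
      a <- jitter_amp * stats::runif(1, 0.05, 0.15)
      th <- stats::runif(1, 0, 2 * pi)
      jt[[length(jt) + 1L]] <- c(j, stats::runif(1, 2.5, 6), a * cos(th),
                                 a * sin(th), stats::runif(1, 0, 2 * pi))
    }
  }
  jt <- do.call(rbind, jt)
  colnames(jt) <- colnames(terms)
  base <- .base_pose(J)
  base <- base + matrix(subject_shift, nrow = J, ncol = 2, byrow = TRUE)
  list(J = J, base = base, terms = rbind(terms, jt), f0 = f0)
}

.imu_map <- function(C, J) {
  sites <- .limb_sites(J)
  types <- c("acc_x", "acc_y", "gyro")
  data.frame(channel = seq_len(C),
             joint = sites[((ceiling(seq_len(C) / 3) - 1L) %% length(sites)) + 1L],
             type = types[((seq_len(C) - 1L) %% 3L) + 1L],
             gravity = types[((seq_len(C) - 1L) %% 3L) + 1L] == "acc_y")
}

.emg_map <- function(C, J) {
  sites <- .limb_sites(J)
  sites[((seq_len(C) - 1L) %% length(sites)) + 1L]
}

# Band-limited noise carrier for EMG channels: white Gaussian noise passed
# through a zero-phase Butterworth band-pass (20-450 Hz at the native rate),
# rescaled to unit standard deviation.
.emg_carrier <- function(n, rate, band = c(20, 450)) {
  hi <- min(band[2], 0.45 * rate)
  lo <- min(band[1], hi / 4)
  w <- stats::rnorm(n)
  if (hi > lo && n > 24) {
    w <- butter_bandpass_apply(w, lo, hi, 4, rate)
  }
  w / max(stats::sd(w), 1e-12)
}

#' Synthesize one multimodal trial
#'
#' Generates a single trial of the emulated acquisition rig. Skeleton
#' trajectories are per-class sums of sinusoidal joint motifs (class-specific
#' frequencies, amplitudes and phase structure) with subject-specific scale,
#' postural jitter and measurement noise. IMU channels are finite-difference
#' second derivatives of designated limb-joint trajectories sampled at the
#' IMU rate (plus a constant 9.81 gravity bias on accelerometer y channels
#' and noise), delayed by the trial's IMU clock offset. EMG channels are
#' band-limited (20-450 Hz) noise amplitude-modulated by a rectified
#' activation envelope proportional to source-joint speed, which leads the
#' kinematics by `cfg$emg_latency`, delayed by the EMG clock offset.
#'
#' @param cfg A [generator_config()].
#' @param subject_id Subject identifier string.
#' @param action_class Integer class in `1..cfg$n_classes`.
#' @param seed Integer seed for this trial's random state.
#' @return A `synthetic_session` with streams, masks, labels, the true
#'   stability score and the injected per-modality clock offsets.
#' @export
synthesize_trial <- function(cfg, subject_id, action_class, seed = 1L) {
  stopif(!inherits(cfg, "generator_config"), "cfg must be a generator_config")
  stopif(!(action_class %in% seq_len(cfg$n_classes)),
         sprintf("unknown action class %s (n_classes = %d)", action_class, cfg$n_classes))
  # subject idiosyncrasy is a function of (dataset seed, subject id) only
  sub <- with_seed(derive_seed(cfg$seed, "subject", subject_id), {
    list(scale = stats::rnorm(1, 1, 0.05), shift = stats::rnorm(2, 0, 0.02))
  })
  with_seed(seed, {
    draw_off <- function() {
      if (identical(cfg$offset_mode, "fixed")) {
        cfg$offset_range * sample(c(-1, 1), 1)
      } else {
        stats::runif(1, -cfg$offset_range, cfg$offset_range)
      }
    }
    off_imu <- draw_off()
    off_emg <- draw_off()
    jitter_amp <- stats::runif(1, 0, cfg$jitter_max)
    model <- .trial_model(cfg, sub$scale, sub$shift, action_class, jitter_amp)

    dur <- cfg$trial_duration
    r <- cfg$rates
    Ts <- round(dur * r[["skeleton"]]); Ti <- round(dur * r[["imu"]])
    Te <- round(dur * r[["emg"]])
    t_s <- (seq_len(Ts) - 1) / r[["skeleton"]]
    t_i <- (seq_len(Ti) - 1) / r[["imu"]]
    t_e <- (seq_len(Te) - 1) / r[["emg"]]

    skeleton <- eval_trajectory(model, t_s)
    skeleton <- skeleton + stats::rnorm(length(skeleton), 0, cfg$noise_floor[["skeleton"]])

    imu_map <- .imu_map(cfg$imu_channels, cfg$n_joints)
    imu_joints <- sort(unique(imu_map$joint))
    # positions on the IMU clock (delayed by the clock offset), then discrete
    # second derivative; `kinematics` keeps the clean sampled trajectories so
    # downstream consistency checks have the exact reference.
    pos_i <- eval_trajectory(model, t_i - off_imu, joints = imu_joints)
    spd_i <- eval_trajectory(model, t_i - off_imu, joints = imu_joints, deriv = 1L)
    imu <- matrix(0, Ti, cfg$imu_channels)
    for (c in seq_len(cfg$imu_channels)) {
      ji <- match(imu_map$joint[c], imu_joints)
      imu[, c] <- switch(imu_map$type[c],
        acc_x = second_difference(pos_i[, ji, 1], r[["imu"]]),
        acc_y = second_difference(pos_i[, ji, 2], r[["imu"]]) + 9.81,
        gyro = sqrt(spd_i[, ji, 1]^2 + spd_i[, ji, 2]^2))
    }
    imu <- imu + stats::rnorm(length(imu), 0, cfg$noise_floor[["imu"]])

    emg_joints_all <- .emg_map(cfg$emg_channels, cfg$n_joints)
    emg_joints <- sort(unique(emg_joints_all))
    # activation envelope: rectified source-joint speed evaluated with the
    # neuromuscular lead, then observed through the EMG clock offset
    spd_e <- eval_trajectory(model, t_e - off_emg + cfg$emg_latency,
                             joints = emg_joints, deriv = 1L)
    emg <- matrix(0, Te, cfg$emg_channels)
    for (c in seq_len(cfg$emg_channels)) {
      ji <- match(emg_joints_all[c], emg_joints)
      spd <- sqrt(spd_e[, ji, 1]^2 + spd_e[, ji, 2]^2)
      # session-specific electrode gain and slow baseline drift: surface EMG
      # amplitude is not stationary across trials, so the envelope pattern
      # (not its absolute scale) is the informative signal
      gain <- exp(stats::rnorm(1, 0, cfg$emg_gain_sd))
      drift_f <- stats::runif(2, 0.1, 0.4)
      drift_ph <- stats::runif(2, 0, 2 * pi)
      drift <- cfg$emg_drift * sqrt(mean(spd^2)) *
        (1 + 0.5 * sin(2 * pi * drift_f[1] * t_e + drift_ph[1]) +
           0.5 * sin(2 * pi * drift_f[2] * t_e + drift_ph[2])) / 2
      env <- 0.05 + drift + spd
      emg[, c] <- gain * env * .emg_carrier(Te, r[["emg"]])
    }
    emg <- emg + stats::rnorm(length(emg), 0, cfg$noise_floor[["emg"]])

    phase <- motif_phase(t_s, model$f0, cfg$phase_count)
    ses <- list(subject_id = subject_id, action_class = as.integer(action_class),
                skeleton = skeleton, imu = imu, emg = emg,
                masks = list(skeleton = matrix(TRUE, Ts, cfg$n_joints),
                             imu = rep(TRUE, Ti), emg = rep(TRUE, Te)),
                rates = r, phase_labels = phase,
                stability_true = 1 - jitter_amp / cfg$jitter_max,
                offsets_true = c(imu = off_imu, emg = off_emg),
                imu_map = imu_map, emg_joints = emg_joints_all,
                kinematics = list(joints = imu_joints, pos = pos_i, times = t_i),
                f0 = model$f0, trial_duration = dur,
                phase_count = cfg$phase_count, n_classes = cfg$n_classes)
    class(ses) <- "synthetic_session"
    ses
  })
}

# Discrete second derivative (central differences, one-sided at the ends).
second_difference <- function(x, rate) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]) * rate^2
  d[1] <- d[2]; d[n] <- d[n - 1]
  d
}

# Phase label: each motif cycle is split into `phases` contiguous segments.
motif_phase <- function(times, f0, phases) {
  as.integer(floor(((times * f0) %% 1) * phases)) + 1L
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf("<synthetic_session> subject %s, class %d, %.1f s\n",
              x$subject_id, x$action_class, x$trial_duration))
  cat(sprintf("  skeleton %d x %d x 2 @ %g Hz | imu %d x %d @ %g Hz | emg %d x %d @ %g Hz\n",
              nrow(x$skeleton), dim(x$skeleton)[2], x$rates[["skeleton"]],
              nrow(x$imu), ncol(x$imu), x$rates[["imu"]],
              nrow(x$emg), ncol(x$emg), x$rates[["emg"]]))
  cat(sprintf("  stability %.3f | offsets imu %+.3f s, emg %+.3f s\n",
              x$stability_true, x$offsets_true[["imu"]], x$offsets_true[["emg"]]))
  invisible(x)
}

#' Generate a balanced multimodal dataset with a subject-independent split
#'
#' Every subject performs `trials_per_subject` repetitions of each action
#' class, so the class histogram is uniform by construction. Subjects are
#' partitioned 70% train / 10% validation / 20% test; no subject appears in
#' two partitions.
#'
#' @param cfg A [generator_config()].
#' @return A `motion_dataset`: list of sessions plus a manifest data frame
#'   (`session_id`, `subject_id`, `class`, `split`).
#' @export
generate_dataset <- function(cfg) {
  stopif(!inherits(cfg, "generator_config"), "cfg must be a generator_config")
  subjects <- sprintf("S%03d", seq_len(cfg$n_subjects))
  n <- cfg$n_subjects
  n_train <- round(0.7 * n); n_val <- round(0.1 * n)
  n_test <- n - n_train - n_val
  stopif(n_train < 1 || n_val < 1 || n_test < 1,
         sprintf("the 70/10/20 subject split needs >= 10 subjects, got %d", n))
  perm <- with_seed(derive_seed(cfg$seed, "split"), sample(n))
  split <- rep(NA_character_, n)
  split[perm[seq_len(n_train)]] <- "train"
  split[perm[n_train + seq_len(n_val)]] <- "val"
  split[perm[n_train + n_val + seq_len(n_test)]] <- "test"

  sessions <- list()
  rows <- list()
  k <- 0L
  for (si in seq_len(n)) {
    for (cl in seq_len(cfg$n_classes)) {
      for (tr in seq_len(cfg$trials_per_subject)) {
        k <- k + 1L
        sid <- sprintf("%s_c%02d_t%02d", subjects[si], cl, tr)
        ses <- synthesize_trial(cfg, subjects[si], cl,
                                seed = derive_seed(cfg$seed, "trial", si, cl, tr))
        ses$session_id <- sid
        sessions[[sid]] <- ses
        rows[[k]] <- data.frame(session_id = sid, subject_id = subjects[si],
                                class = cl, split = split[si],
                                stringsAsFactors = FALSE)
      }
    }
  }
  out <- list(sessions = sessions, manifest = do.call(rbind, rows), cfg = cfg)
  class(out) <- "motion_dataset"
  out
}

#' @export
print.motion_dataset <- function(x, ...) {
  tab <- table(x$manifest$split)
  cat(sprintf("<motion_dataset> %d sessions, %d subjects, %d classes (%s)\n",
              nrow(x$manifest), length(unique(x$manifest$subject_id)),
              x$cfg$n_classes,
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Specify a controlled perturbation
#'
#' Encodes the quantified robustness conditions: random joint occlusion
#' (30-50% of joints per frame), viewpoint rotation (+-15 degrees), additive
#' white Gaussian sensor noise at a stated SNR, or total loss of one
#' modality.
#'
#' @param kind One of `"occlusion"`, `"viewpoint"`, `"sensor_noise"`,
#'   `"modality_loss"`, `"none"`.
#' @param occlusion_fraction Fraction of joints masked per frame.
#' @param rotation_deg Rotation bound in degrees.
#' @param snr_db Signal-to-noise ratio of the injected noise in dB.
#' @param lost_modality Which stream is lost entirely.
#' @return A `perturbation_spec`.
#' @export
perturbation_spec <- function(kind = c("none", "occlusion", "viewpoint",
                                       "sensor_noise", "modality_loss"),
                              occlusion_fraction = 0.4, rotation_deg = 15,
                              snr_db = 20,
                              lost_modality = c("skeleton", "imu", "emg")) {
  kind <- match.arg(kind)
  spec <- list(kind = kind)
  if (kind == "occlusion") {
    stopif(any(occlusion_fraction < 0) || any(occlusion_fraction > 1),
           "occlusion_fraction must be in [0, 1]")
    stopif(!length(occlusion_fraction) %in% 1:2,
           "occlusion_fraction must be a scalar or a (min, max) range")
    spec$occlusion_fraction <- occlusion_fraction
  } else if (kind == "viewpoint") {
    spec$rotation_deg <- rotation_deg
  } else if (kind == "sensor_noise") {
    spec$snr_db <- snr_db
  } else if (kind == "modality_loss") {
    spec$lost_modality <- match.arg(lost_modality)
  }
  class(spec) <- "perturbation_spec"
  spec
}

#' Apply a controlled perturbation to a session
#'
#' Labels are never altered; corruption is reflected in the validity masks
#' where applicable (occluded joints, lost modalities).
#'
#' @param session A `synthetic_session`.
#' @param spec A [perturbation_spec()].
#' @param seed Integer seed for the perturbation's randomness.
#' @return The perturbed `synthetic_session`.
#' @export
perturb <- function(session, spec, seed = 1L) {
  stopif(!inherits(spec, "perturbation_spec"), "spec must be a perturbation_spec")
  if (spec$kind == "none") return(session)
  with_seed(seed, {
    if (spec$kind == "occlusion") {
      J <- dim(session$skeleton)[2]
      frac <- spec$occlusion_fraction
      for (t in seq_len(nrow(session$skeleton))) {
        # a (min, max) fraction range is redrawn per frame
        f_t <- if (length(frac) == 2) stats::runif(1, frac[1], frac[2]) else frac
        n_occ <- round(f_t * J)
        hit <- sample(J, n_occ)
        session$skeleton[t, hit, ] <- 0
        session$masks$skeleton[t, hit] <- FALSE
      }
    } else if (spec$kind == "viewpoint") {
      # one rotation per call: a viewpoint shift is constant over the trial
      ang <- stats::runif(1, -spec$rotation_deg, spec$rotation_deg) * pi / 180
      R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
      for (t in seq_len(nrow(session$skeleton))) {
        v <- session$masks$skeleton[t, ]
        if (!any(v)) next
        xy <- matrix(session$skeleton[t, , ], ncol = 2)
        ctr <- colMeans(xy[v, , drop = FALSE])
        rot <- sweep(xy, 2, ctr) %*% t(R)
        session$skeleton[t, , ] <- sweep(rot, 2, ctr, "+")
      }
    } else if (spec$kind == "sensor_noise") {
      add_awgn <- function(x, snr_db) {
        p_sig <- colMeans(x^2)
        sd_n <- sqrt(p_sig / 10^(snr_db / 10))
        x + matrix(stats::rnorm(length(x)), nrow(x), ncol(x)) %*% diag(sd_n, ncol(x))
      }
      session$imu <- add_awgn(session$imu, spec$snr_db)
      session$emg <- add_awgn(session$emg, spec$snr_db)
    } else if (spec$kind == "modality_loss") {
      m <- spec$lost_modality
      if (m == "skeleton") {
        session$skeleton[] <- 0
        session$masks$skeleton[] <- FALSE
      } else {
        session[[m]][] <- 0
        session$masks[[m]][] <- FALSE
      }
    }
    session
  })
}

#' Write/read a session as a plain-text container
#'
#' One directory per session: CSV matrices for the three streams and the
#' skeleton mask, plus a JSON sidecar with rates, labels and offsets.
#'
#' @param session A `synthetic_session`.
#' @param path Directory to create.
#' @export
write_session <- function(session, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  sk <- session$skeleton
  sk2 <- matrix(sk, nrow = dim(sk)[1])
  utils::write.csv(sk2, file.path(path, "skeleton.csv"), row.names = FALSE)
  utils::write.csv(session$imu, file.path(path, "imu.csv"), row.names = FALSE)
  utils::write.csv(session$emg, file.path(path, "emg.csv"), row.names = FALSE)
  utils::write.csv(session$masks$skeleton * 1L, file.path(path, "mask_skeleton.csv"),
                   row.names = FALSE)
  meta <- session[c("subject_id", "session_id", "action_class", "rates",
                    "phase_labels", "stability_true", "offsets_true", "f0",
                    "trial_duration", "phase_count", "n_classes")]
  # named atomic vectors lose their names as JSON arrays; store as objects
  meta$rates <- as.list(meta$rates)
  meta$offsets_true <- as.list(meta$offsets_true)
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_session
#' @param path Directory written by [write_session()].
#' @export
read_session <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  sk2 <- as.matrix(utils::read.csv(file.path(path, "skeleton.csv")))
  J <- ncol(sk2) / 2
  ses <- list(subject_id = meta$subject_id, session_id = meta$session_id,
              action_class = as.integer(meta$action_class),
              skeleton = array(sk2, dim = c(nrow(sk2), J, 2)),
              imu = unname(as.matrix(utils::read.csv(file.path(path, "imu.csv")))),
              emg = unname(as.matrix(utils::read.csv(file.path(path, "emg.csv")))),
              rates = unlist(meta$rates), phase_labels = as.integer(meta$phase_labels),
              stability_true = meta$stability_true,
              offsets_true = unlist(meta$offsets_true), f0 = meta$f0,
              trial_duration = meta$trial_duration,
              phase_count = as.integer(meta$phase_count),
              n_classes = as.integer(meta$n_classes))
  msk <- as.matrix(utils::read.csv(file.path(path, "mask_skeleton.csv"))) > 0
  ses$masks <- list(skeleton = unname(msk),
                    imu = rep(TRUE, nrow(ses$imu)), emg = rep(TRUE, nrow(ses$emg)))
  class(ses) <- "synthetic_session"
  ses
}
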