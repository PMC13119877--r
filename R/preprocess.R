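# Preprocessing chain: keypoint normalization, Butterworth band-pass,
# Z-score standardization, cubic-spline resampling to a unified temporal
# grid, and fixed-length windowing.

#' Preprocessing configuration
#'
#' @param grid_rate Unified temporal grid rate in Hz. The acquisition-scale
#'   default is 1000 Hz (all streams upsampled to the EMG clock); the
#'   semantics are rate-agnostic and tests run a lighter grid.
#' @param window_seconds,window_stride_seconds Sliding-window length and hop.
#' @param bandpass `(low, high)` Butterworth band edges in Hz for the EMG
#'   stream.
#' @param bandpass_order Butterworth order (applied zero-phase, so the
#'   effective magnitude response is squared).
#' @param scale_reference Reference length for keypoint normalization:
#'   `"torso_length"` (mid-shoulder to mid-hip; more occlusion-robust) or
#'   `"shoulder_width"`.
#' @param emg_envelope `"auto"` (default), `TRUE` or `FALSE`. When the
#'   unified grid undersamples the EMG band (`grid_rate < 2 * high`), the
#'   band-passed EMG is reduced to its linear envelope (full-wave
#'   rectification + low-pass) before resampling, the standard
#'   anti-aliasing treatment for decimated surface EMG.
#' @param imu_bandpass Apply the band-pass to IMU channels too (off by
#'   default; IMU channels are only Z-scored).
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(grid_rate = 1000, window_seconds = 4,
                              window_stride_seconds = window_seconds,
                              bandpass = c(20, 450), bandpass_order = 4,
                              scale_reference = c("torso_length", "shoulder_width"),
                              emg_envelope = "auto", imu_bandpass = FALSE) {
  stopif(grid_rate <= 0, "grid_rate must be positive")
  stopif(!(bandpass[1] > 0 && bandpass[1] < bandpass[2]),
         "need 0 < low < high band edges")
  stopif(window_stride_seconds > window_seconds,
         "window stride must not exceed window length")
  cfg <- list(grid_rate = grid_rate, window_seconds = window_seconds,
              window_stride_seconds = window_stride_seconds,
              bandpass = bandpass, bandpass_order = bandpass_order,
              scale_reference = match.arg(scale_reference),
              emg_envelope = emg_envelope, imu_bandpass = imu_bandpass)
  class(cfg) <- "preprocess_config"
  cfg
}

# Butterworth band-pass realized as cascaded high-pass and low-pass
# sections of the stated order, each applied zero-phase. The single
# polynomial-form band-pass of order n is an ill-conditioned 2n-pole filter
# when the upper edge sits near Nyquist; the cascade is numerically exact
# (in-band gain 1 to well below 0.1%), the standard realization in EMG
# pipelines.
butter_bandpass_apply <- function(x, lo, hi, order, rate) {
  hp <- signal::butter(order, lo / (rate / 2), type = "high")
  lp <- signal::butter(order, hi / (rate / 2), type = "low")
  zero_phase_filter(lp, zero_phase_filter(hp, x))
}

# Zero-phase IIR filtering with odd-reflection edge padding (forward pass,
# time reversal, second pass). Padding suppresses the start-up transients a
# plain forward-backward pass leaves on short records.
zero_phase_filter <- function(filt, x) {
  n <- length(x)
  # padding long enough for the slowest pole's transient to die off
  pad <- min(150L * (max(length(filt$b), length(filt$a)) - 1L), n - 1L)
  xp <- c(2 * x[1] - rev(x[2:(pad + 1)]), x, 2 * x[n] - rev(x[(n - pad):(n - 1)]))
  y <- signal::filter(filt, xp)
  y <- rev(signal::filter(filt, rev(y)))
  as.numeric(y[(pad + 1):(pad + n)])
}

.ref_joints <- function(J) {
  if (J >= 13L) list(shoulders = c(6L, 7L), hips = c(12L, 13L))
  else list(shoulders = c(1L, min(2L, J)), hips = c(max(J - 1L, 1L), J))
}

#' Normalize skeleton keypoints per frame
#'
#' Maps every frame to a canonical scale: coordinates are centred on the
#' valid-joint centroid and divided by a per-frame reference length (torso
#' length or shoulder width). Frames with a degenerate scale (all joints
#' coincident, or fewer than two distinct valid joints) are flagged invalid
#' rather than divided. Invalid joints propagate: their coordinates are
#' zeroed and their mask entries stay `FALSE`.
#'
#' @param frames `[T, J, 2]` array (or a single `[J, 2]` frame).
#' @param scale_reference `"torso_length"` or `"shoulder_width"`. If the
#'   reference joints are occluded in a frame, the scale falls back to twice
#'   the RMS distance of the valid joints to their centroid.
#' @param mask Optional `[T, J]` logical validity mask.
#' @param eps Degeneracy threshold on the reference length.
#' @return `[T, J, 2]` array of normalized coordinates with attribute
#'   `"mask"` (the updated validity mask).
#' @export
normalize_keypoints <- function(frames, scale_reference = c("torso_length", "shoulder_width"),
                                mask = NULL, eps = 1e-8) {
  scale_reference <- match.arg(scale_reference)
  single <- length(dim(frames)) == 2L
  if (single) frames <- array(frames, dim = c(1L, dim(frames)))
  Tn <- dim(frames)[1]; J <- dim(frames)[2]
  if (is.null(mask)) mask <- matrix(TRUE, Tn, J)
  out <- array(0, dim = dim(frames))
  ref <- .ref_joints(J)
  for (t in seq_len(Tn)) {
    v <- mask[t, ]
    xy <- frames[t, , , drop = TRUE]
    if (J == 1L) xy <- matrix(xy, 1L, 2L)
    distinct <- if (sum(v) >= 2) nrow(unique(round(xy[v, , drop = FALSE], 12))) else 0L
    if (distinct < 2L) { mask[t, ] <- FALSE; next }
    ctr <- colMeans(xy[v, , drop = FALSE])
    sc <- NA_real_
    if (scale_reference == "torso_length" && all(v[c(ref$shoulders, ref$hips)])) {
      ms <- colMeans(xy[ref$shoulders, , drop = FALSE])
      mh <- colMeans(xy[ref$hips, , drop = FALSE])
      sc <- sqrt(sum((ms - mh)^2))
    } else if (scale_reference == "shoulder_width" && all(v[ref$shoulders])) {
      sc <- sqrt(sum((xy[ref$shoulders[1], ] - xy[ref$shoulders[2], ])^2))
    }
    if (!is.finite(sc) || sc < eps) {
      sc <- 2 * sqrt(mean(rowSums(sweep(xy[v, , drop = FALSE], 2, ctr)^2)))
    }
    if (sc < eps) { mask[t, ] <- FALSE; next }
    nrm <- sweep(xy, 2, ctr) / sc
    nrm[!v, ] <- 0
    out[t, , ] <- nrm
  }
  if (single) out <- array(out[1, , ], dim = dim(frames)[2:3])
  attr(out, "mask") <- mask
  out
}

#' Filter and standardize a sensor stream
#'
#' EMG: zero-phase Butterworth band-pass of the configured order and band,
#' optional linear-envelope extraction (see [preprocess_config()]), then
#' per-channel Z-score. IMU: Z-score only (band-pass via
#' `cfg$imu_bandpass`). Skeleton streams pass through untouched (they are
#' normalized geometrically). When `stats` is supplied (training-partition
#' means/sds), those frozen statistics are used instead of self-statistics,
#' preventing leakage under the subject-independent protocol.
#'
#' @param stream `[T, C]` numeric matrix.
#' @param rate Sampling rate of `stream` in Hz.
#' @param cfg A [preprocess_config()].
#' @param modality `"emg"`, `"imu"` or `"skeleton"`.
#' @param stats Optional `list(mean=, sd=)` per-channel statistics.
#' @param standardize Apply the Z-score step (disable to inspect the raw
#'   filter response).
#' @return Filtered, standardized `[T, C]` matrix.
#' @export
filter_standardize <- function(stream, rate, cfg, modality = c("emg", "imu", "skeleton"),
                               stats = NULL, standardize = TRUE) {
  modality <- match.arg(modality)
  if (modality == "skeleton") return(stream)
  stream <- as.matrix(stream)
  stopif(nrow(stream) <= 3 * cfg$bandpass_order,
         "stream too short for the configured filter order")
  do_bp <- (modality == "emg") || isTRUE(cfg$imu_bandpass)
  if (do_bp) {
    lo <- cfg$bandpass[1]; hi <- cfg$bandpass[2]
    stopif(hi >= rate / 2, sprintf(
      "band edge %g Hz is at or above the Nyquist frequency %g Hz", hi, rate / 2))
    for (c in seq_len(ncol(stream))) {
      stream[, c] <- butter_bandpass_apply(stream[, c], lo, hi,
                                           cfg$bandpass_order, rate)
    }
    want_env <- isTRUE(cfg$emg_envelope) ||
      (identical(cfg$emg_envelope, "auto") && cfg$grid_rate < 2 * hi)
    if (modality == "emg" && want_env) {
      lp_cut <- min(0.4 * cfg$grid_rate, 10)
      lp <- signal::butter(2, lp_cut / (rate / 2), type = "low")
      for (c in seq_len(ncol(stream))) {
        stream[, c] <- zero_phase_filter(lp, abs(stream[, c]))
      }
    }
  }
  if (standardize) {
    mu <- if (!is.null(stats)) stats$mean else colMeans(stream)
    sd <- if (!is.null(stats)) stats$sd else apply(stream, 2, stats::sd)
    sd[sd < 1e-12] <- 1
    stream <- sweep(sweep(stream, 2, mu), 2, sd, "/")
  }
  stream
}

#' Resample a stream onto the unified temporal grid
#'
#' Per-channel cubic-spline interpolation (Forsythe end conditions, which
#' reproduce cubic polynomials exactly) evaluated on a uniform grid sharing
#' time zero with the source. The grid never extends beyond the last source
#' sample, so no extrapolation occurs.
#'
#' @param stream `[T, C]` matrix or length-`T` vector.
#' @param src_rate,grid_rate Source and target rates in Hz.
#' @return `[T_g, C]` matrix with attribute `"times"` (grid timestamps).
#' @export
resample_to_grid <- function(stream, src_rate, grid_rate) {
  stopif(grid_rate <= 0, "grid_rate must be positive")
  stream <- as.matrix(stream)
  Tn <- nrow(stream)
  stopif(Tn < 4, "need at least 4 samples for cubic-spline resampling")
  t_src <- (seq_len(Tn) - 1) / src_rate
  n_g <- floor(t_src[Tn] * grid_rate) + 1
  t_g <- (seq_len(n_g) - 1) / grid_rate
  out <- matrix(0, n_g, ncol(stream))
  for (c in seq_len(ncol(stream))) {
    sf <- stats::splinefun(t_src, stream[, c], method = "fmm")
    out[, c] <- sf(t_g)
  }
  attr(out, "times") <- t_g
  out
}

# Categorical labels move to the grid by nearest source frame (labels are
# categorical, interpolation would be meaningless).
resample_labels <- function(labels, src_rate, grid_times) {
  idx <- pmin(pmax(round(grid_times * src_rate) + 1, 1), length(labels))
  labels[idx]
}

#' Preprocess a session onto the unified grid
#'
#' Runs the full chain: keypoint normalization, per-modality filtering and
#' standardization at the native rates, cubic-spline resampling of all
#' streams to `cfg$grid_rate`, nearest-frame phase-label mapping, and
#' sliding-window segmentation.
#'
#' @param session A `synthetic_session` (or any list with the same fields).
#' @param cfg A [preprocess_config()].
#' @param stats Optional frozen normalization statistics from
#'   [compute_norm_stats()] (train partition).
#' @return List of `unified_window` objects.
#' @export
preprocess_session <- function(session, cfg, stats = NULL) {
  r <- session$rates
  sk <- normalize_keypoints(session$skeleton, cfg$scale_reference,
                            mask = session$masks$skeleton)
  sk_mask <- attr(sk, "mask")
  J <- dim(sk)[2]
  imu <- filter_standardize(session$imu, r[["imu"]], cfg, "imu", stats$imu)
  emg <- filter_standardize(session$emg, r[["emg"]], cfg, "emg", stats$emg)

  sk_flat <- matrix(sk, nrow = dim(sk)[1])
  sk_g <- resample_to_grid(sk_flat, r[["skeleton"]], cfg$grid_rate)
  t_g <- attr(sk_g, "times")
  imu_g <- resample_to_grid(imu, r[["imu"]], cfg$grid_rate)
  emg_g <- resample_to_grid(emg, r[["emg"]], cfg$grid_rate)
  Tg <- min(nrow(sk_g), nrow(imu_g), nrow(emg_g))
  t_g <- t_g[seq_len(Tg)]

  sk_idx <- pmin(pmax(round(t_g * r[["skeleton"]]) + 1, 1), nrow(sk_mask))
  skm_g <- sk_mask[sk_idx, , drop = FALSE]
  sk_arr <- array(sk_g[seq_len(Tg), ], dim = c(Tg, J, 2))
  for (j in seq_len(J)) {           # splines may wiggle through masked gaps
    bad <- !skm_g[, j]
    if (any(bad)) sk_arr[bad, j, ] <- 0
  }
  imu_idx <- pmin(pmax(round(t_g * r[["imu"]]) + 1, 1), length(session$masks$imu))
  emg_idx <- pmin(pmax(round(t_g * r[["emg"]]) + 1, 1), length(session$masks$emg))

  gs <- list(skeleton = sk_arr, imu = imu_g[seq_len(Tg), , drop = FALSE],
             emg = emg_g[seq_len(Tg), , drop = FALSE],
             masks = list(skeleton = skm_g,
                          imu = session$masks$imu[imu_idx],
                          emg = session$masks$emg[emg_idx]),
             grid_rate = cfg$grid_rate,
             phase = resample_labels(session$phase_labels, r[["skeleton"]], t_g),
             action_class = session$action_class,
             stability = session$stability_true,
             subject_id = session$subject_id,
             session_id = session$session_id %||% "session")
  segment_windows(gs, cfg)
}

#' Cut a grid-rate session into fixed-length windows
#'
#' @param gs A grid-rate session as produced inside [preprocess_session()].
#' @param cfg A [preprocess_config()].
#' @return List of `unified_window` objects (possibly empty, with a warning,
#'   when the session is shorter than one window).
#' @export
segment_windows <- function(gs, cfg) {
  win <- round(cfg$window_seconds * gs$grid_rate)
  hop <- max(1L, round(cfg$window_stride_seconds * gs$grid_rate))
  Tg <- nrow(gs$imu)
  if (Tg < win) {
    warning(sprintf("session %s shorter than one window; no windows emitted",
                    gs$session_id))
    return(list())
  }
  starts <- seq(1L, Tg - win + 1L, by = hop)
  lapply(starts, function(s) {
    ix <- s:(s + win - 1L)
    w <- list(skeleton = gs$skeleton[ix, , , drop = FALSE],
              imu = gs$imu[ix, , drop = FALSE],
              emg = gs$emg[ix, , drop = FALSE],
              masks = list(skeleton = gs$masks$skeleton[ix, , drop = FALSE],
                           imu = gs$masks$imu[ix], emg = gs$masks$emg[ix]),
              grid_rate = gs$grid_rate, action_class = gs$action_class,
              phase = gs$phase[ix], stability = gs$stability,
              subject_id = gs$subject_id, session_id = gs$session_id,
              start_time = (s - 1) / gs$grid_rate)
    class(w) <- "unified_window"
    w
  })
}

#' @export
print.unified_window <- function(x, ...) {
  cat(sprintf("<unified_window> %s @ %.2fs: %d grid samples @ %g Hz, class %d\n",
              x$session_id, x$start_time, nrow(x$imu), x$grid_rate, x$action_class))
  invisible(x)
}

#' Training-partition normalization statistics
#'
#' Computes frozen per-channel mean/sd of the filtered IMU and EMG streams
#' over a set of (training) sessions, to be passed as `stats` to
#' [preprocess_session()] for all partitions.
#'
#' @param sessions List of sessions.
#' @param cfg A [preprocess_config()].
#' @return `list(imu = list(mean, sd), emg = list(mean, sd))`.
#' @export
compute_norm_stats <- function(sessions, cfg) {
  acc <- function(mod) {
    xs <- lapply(sessions, function(s)
      filter_standardize(s[[mod]], s$rates[[mod]], cfg, mod, standardize = FALSE))
    x <- do.call(rbind, xs)
    list(mean = colMeans(x), sd = pmax(apply(x, 2, stats::sd), 1e-12))
  }
  list(imu = acc("imu"), emg = acc("emg"))
}

#' Preprocess a whole dataset into labelled windows
#'
#' Applies [compute_norm_stats()] on the training partition and
#' [preprocess_session()] everywhere, preserving the manifest split.
#'
#' @param dataset A `motion_dataset` from [generate_dataset()].
#' @param cfg A [preprocess_config()].
#' @param sessions Optional replacement session list (e.g. perturbed copies)
#'   sharing the dataset's manifest.
#' @return `list(windows=, split=, manifest=, stats=)` where `split` is the
#'   per-window partition label.
#' @export
build_windows <- function(dataset, cfg, sessions = NULL) {
  sessions <- sessions %||% dataset$sessions
  man <- dataset$manifest
  train_ids <- man$session_id[man$split == "train"]
  stats <- compute_norm_stats(sessions[train_ids], cfg)
  windows <- list(); split <- character(0)
  for (i in seq_len(nrow(man))) {
    ws <- preprocess_session(sessions[[man$session_id[i]]], cfg, stats)
    windows <- c(windows, ws)
    split <- c(split, rep(man$split[i], length(ws)))
  }
  list(windows = windows, split = split, manifest = man, stats = stats)
}
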