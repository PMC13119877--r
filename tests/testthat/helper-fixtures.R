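# Shared fixtures. Heavy objects (datasets, trained models) are built once
# per test session and memoized.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# A synthetic window with random content (not from the generator) for
# shape-level tests of encoders/model.
random_window <- function(seed = 1, Tg = 48L, J = 17L, CI = 9L, CE = 8L,
                          grid_rate = 24, n_classes = 12L, P = 4L) {
  with_seed(seed, {
    w <- list(skeleton = array(stats::rnorm(Tg * J * 2), dim = c(Tg, J, 2)),
              imu = matrix(stats::rnorm(Tg * CI), Tg, CI),
              emg = matrix(stats::rnorm(Tg * CE), Tg, CE),
              masks = list(skeleton = matrix(TRUE, Tg, J),
                           imu = rep(TRUE, Tg), emg = rep(TRUE, Tg)),
              grid_rate = grid_rate,
              action_class = sample(n_classes, 1),
              phase = sample(P, Tg, replace = TRUE),
              stability = stats::runif(1),
              subject_id = "S1", session_id = "fixture", start_time = 0)
    class(w) <- "unified_window"
    w
  })
}

# Tiny model configuration for gradient checks and wiring tests.
tiny_model_config <- function(...) {
  desk_model_config(d_model = 16L, token_rate = 2, window_seconds = 2,
                    n_classes = 4L,
                    skeleton = list(layers = 1L, heads = 2L, ffn = 24L),
                    imu = list(layers = 1L, hidden = 6L),
                    emg = list(kernel = 3L, dilations = c(1L, 2L)),
                    align = list(window_radius = 1L, heads = 2L, layers = 1L),
                    backbone = list(layers = 1L, heads = 2L, ffn = 24L),
                    fusion_hidden = 6L, ...)
}

tiny_window <- function(seed = 1) {
  random_window(seed, Tg = 16L, J = 5L, CI = 3L, CE = 2L, grid_rate = 8,
                n_classes = 4L, P = 4L)
}

tiny_model_config_dims <- function() {
  tiny_model_config(n_joints = 5L, imu_channels = 3L, emg_channels = 2L,
                    phase_count = 4L, dropout = 0)
}

# Central finite-difference gradient of f at x (arrays or scalars).
numgrad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    x1 <- x; x2 <- x
    x1[i] <- x1[i] + eps
    x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

# Replace NULL gradient leaves with zeros so a gradient tree can be
# flattened parallel to its parameter tree.
grad_fill0 <- function(p, g) {
  if (is.list(p)) {
    nms <- names(p)
    for (i in seq_along(p)) {
      key <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else i
      p[[i]] <- grad_fill0(p[[i]], g[[key]])
    }
    return(p)
  }
  if (is.null(g)) p * 0 else g
}

# Small 4-class dataset for optimizer-level tests.
small_train_data <- function() {
  cached("small_train_data", {
    ds <- generate_dataset(generator_config(n_subjects = 10, n_classes = 4,
                                            trial_duration = 4, seed = 21))
    build_windows(ds, preprocess_config(grid_rate = 24, window_seconds = 2,
                                        window_stride_seconds = 2))
  })
}

# ---- shared study-scale fixtures for the acceptance suite ------------------

# Dataset at the end-to-end evaluation scale: 20 subjects x 12 classes,
# 10 s trials cut into five 2 s windows (1200 windows).
acc_preprocess_config <- function() {
  # 16 Hz grid: every informative component of the synthetic streams lies
  # below 5 Hz, and the lighter grid keeps the trained fixtures fast
  preprocess_config(grid_rate = 16, window_seconds = 2, window_stride_seconds = 2)
}

acc_dataset <- function() {
  cached("acc_dataset", {
    gcfg <- generator_config(n_subjects = 20, trials_per_subject = 1,
                             trial_duration = 10, seed = 101)
    generate_dataset(gcfg)
  })
}

acc_windows <- function() {
  cached("acc_windows", build_windows(acc_dataset(), acc_preprocess_config()))
}

# Full model trained on the clean dataset (validation accuracy saturates
# within the first ten epochs at this scale).
acc_fit <- function() {
  cached("acc_fit", {
    fit(acc_windows(), desk_model_config(),
        desk_train_config(epochs = 12L, lr_start = 1.5e-3, batch_size = 64L,
                          patience = 12L, seed = 7))
  })
}

# Subject subset of the shared dataset (8 train + 1 val subjects; the
# manifest's test subjects untouched) for the fusion-vs-uniform robustness
# comparison: reuses the already-preprocessed windows.
acc_subset_data <- function() {
  cached("acc_subset_data", {
    dat <- acc_windows()
    man <- acc_dataset()$manifest
    subj <- vapply(dat$windows, `[[`, character(1), "subject_id")
    train_subj <- sort(unique(man$subject_id[man$split == "train"]))
    sub_train <- train_subj[1:9]
    sub_val <- train_subj[10]
    keep <- (subj %in% sub_train & dat$split == "train") |
      (subj %in% sub_val) | dat$split == "test"
    list(windows = dat$windows[keep],
         split = ifelse(subj[keep] %in% sub_train, "train",
                        ifelse(subj[keep] %in% sub_val, "val", "test")))
  })
}

# Perturbed copies of the shared test sessions, preprocessed once per
# condition with the frozen training statistics.
acc_perturbed_windows <- function() {
  cached("acc_perturbed_windows", {
    ds <- acc_dataset()
    dat <- acc_windows()
    pp <- acc_preprocess_config()
    test_ids <- ds$manifest$session_id[ds$manifest$split == "test"]
    prot <- robustness_protocol()
    out <- lapply(names(prot), function(nm) {
      wl <- list()
      for (sid in test_ids) {
        ses <- perturb(ds$sessions[[sid]], prot[[nm]],
                       seed = derive_seed(55, nm, sid))
        wl <- c(wl, preprocess_session(ses, pp, dat$stats))
      }
      wl
    })
    names(out) <- names(prot)
    out
  })
}

# Trained models for the robustness comparison, memoized per (variant, seed).
acc_c6_fit <- function(variant, seed) {
  cached(paste0("acc_c6_fit_", variant, "_", seed), {
    fit(acc_subset_data(), desk_model_config(d_model = 48L),
        desk_train_config(epochs = 12L, lr_start = 1.5e-3, batch_size = 64L,
                          patience = 12L, seed = seed),
        variant = variant)
  })
}

# Smaller dataset with fixed-magnitude 3-token inter-modality clock offsets
# (3 tokens at 8 Hz = 0.375 s) for the ablation/robustness runs.
offset_dataset <- function() {
  cached("offset_dataset", {
    gcfg <- generator_config(n_subjects = 10, trials_per_subject = 1,
                             trial_duration = 6, offset_range = 0.375,
                             offset_mode = "fixed", seed = 202)
    generate_dataset(gcfg)
  })
}

offset_windows <- function() {
  cached("offset_windows", build_windows(offset_dataset(), acc_preprocess_config()))
}

# One trained model per (variant, seed) on the offset dataset, memoized so
# the ablation and robustness criteria share them.
offset_model_config <- function() desk_model_config(d_model = 48L)

offset_fit <- function(variant, seed) {
  cached(paste0("offset_fit_", variant, "_", seed), {
    fit(offset_windows(), offset_model_config(),
        desk_train_config(epochs = 8L, lr_start = 1.5e-3, batch_size = 42L,
                          patience = 8L, seed = seed),
        variant = variant)
  })
}
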