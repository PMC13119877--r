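# Training protocol: AdamW with decoupled weight decay, cosine-annealed
# learning rate, modality dropout (+ optional noise augmentation), early
# stopping on validation loss, under the subject-independent split with
# k-fold cross-validation over the training/validation subjects.

#' Training configuration
#'
#' Reference protocol: AdamW with weight decay 1e-2, cosine annealing from
#' 1e-4 to 1e-6, batch size 32, 150 epochs, dropout 0.1, modality dropout
#' 0.2, five folds. `desk_train_config()` scales the schedule for CPU-sized
#' experiments.
#'
#' @param lr_start,lr_end Cosine schedule endpoints.
#' @param weight_decay Decoupled weight decay (weight matrices only).
#' @param batch_size Windows per minibatch.
#' @param epochs Maximum epochs.
#' @param modality_dropout_p Per-modality drop probability during training
#'   (sensor modalities only unless `dropout_include_skeleton`).
#' @param dropout_include_skeleton Allow dropping the visual anchor too.
#' @param noise_aug_p Probability of injecting additive Gaussian noise into
#'   each sensor stream of a training window (uncertainty heads need
#'   exposure to degraded inputs to calibrate their weighting).
#' @param noise_aug_snr SNR range (dB) for the noise augmentation.
#' @param lambdas Loss weights `list(cls=, phase=, stab=, smooth=, unc=)`;
#'   `unc` weights the uncertainty-calibration margin term that makes
#'   synthetically corrupted training streams score higher uncertainty than
#'   clean ones.
#' @param folds Cross-validation folds over the train+validation subjects.
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement).
#' @param seed Integer seed governing initialization, shuffling and
#'   augmentation.
#' @return A `train_config` list.
#' @export
train_config <- function(lr_start = 1e-4, lr_end = 1e-6, weight_decay = 1e-2,
                         batch_size = 32L, epochs = 150L,
                         modality_dropout_p = 0.2,
                         dropout_include_skeleton = FALSE,
                         noise_aug_p = 0.25, noise_aug_snr = c(0, 20),
                         lambdas = list(cls = 1, phase = 1, stab = 0.5,
                                        smooth = 0.01, unc = 0.3),
                         folds = 5L, patience = 15L, seed = 1L) {
  stopif(lr_end > lr_start, "lr_end must not exceed lr_start")
  stopif(modality_dropout_p < 0 || modality_dropout_p > 1,
         "modality_dropout_p must be in [0, 1]")
  cfg <- list(lr_start = lr_start, lr_end = lr_end, weight_decay = weight_decay,
              batch_size = as.integer(batch_size), epochs = as.integer(epochs),
              modality_dropout_p = modality_dropout_p,
              dropout_include_skeleton = isTRUE(dropout_include_skeleton),
              noise_aug_p = noise_aug_p, noise_aug_snr = noise_aug_snr,
              lambdas = lambdas, folds = as.integer(folds),
              patience = as.integer(patience), seed = as.integer(seed))
  class(cfg) <- "train_config"
  cfg
}

#' Desk-scale training preset
#'
#' Shorter schedule with a proportionally larger learning rate for small
#' models and datasets: 25 epochs, cosine 1e-3 to 1e-5, single fold.
#'
#' @param ... Overrides forwarded to [train_config()].
#' @return A `train_config`.
#' @export
desk_train_config <- function(...) {
  args <- list(...)
  defaults <- list(lr_start = 1e-3, lr_end = 1e-5, epochs = 25L, folds = 1L,
                   patience = 10L)
  defaults[names(args)] <- args
  do.call(train_config, defaults)
}

# Training-time augmentation of one window (modality dropout + noise).
.augment_window <- function(w, tc, seed) {
  with_seed(seed, {
    if (tc$modality_dropout_p > 0) {
      w <- apply_modality_dropout(w, tc$modality_dropout_p,
                                  seed = derive_seed(seed, "md"),
                                  include_skeleton = tc$dropout_include_skeleton)
    }
    noised <- character(0)
    for (m in c("imu", "emg")) {
      if (stats::runif(1) < tc$noise_aug_p && any(w$masks[[m]])) {
        snr <- stats::runif(1, tc$noise_aug_snr[1], tc$noise_aug_snr[2])
        p_sig <- pmax(colMeans(w[[m]]^2), 1e-12)
        sd_n <- sqrt(p_sig / 10^(snr / 10))
        w[[m]] <- w[[m]] + matrix(stats::rnorm(length(w[[m]])), nrow(w[[m]])) %*%
          diag(sd_n, ncol(w[[m]]))
        noised <- c(noised, m)
      }
    }
    attr(w, "noised") <- noised
    w
  })
}

.window_subjects <- function(windows) vapply(windows, `[[`, character(1), "subject_id")

#' Train the multimodal model
#'
#' End-to-end training under the subject-independent protocol: the test
#' partition (from the manifest) is never touched; the train+validation
#' subjects are re-partitioned per fold, the validation fold drives early
#' stopping, and per-fold results are summarized as mean and sd. Aborts if
#' any subject appears in more than one partition.
#'
#' @param data Window set from [build_windows()].
#' @param model_cfg A [model_config()].
#' @param tc A [train_config()].
#' @param variant Architecture variant (see [run_ablation()]);
#'   `"no_mdrop"` trains the full architecture without modality dropout.
#' @param permute_labels Permute training/validation class labels (negative
#'   control; test labels untouched).
#' @param verbose Print per-epoch progress.
#' @return A `motionfuse_fit`: per-fold `params`, `log`, `best_epoch`, plus
#'   a cross-fold `summary` data frame.
#' @export
fit <- function(data, model_cfg, tc = desk_train_config(), variant = "full",
                permute_labels = FALSE, verbose = FALSE) {
  arch_variant <- if (variant == "no_mdrop") "full" else variant
  if (variant == "no_mdrop") tc$modality_dropout_p <- 0
  windows <- data$windows
  split <- data$split
  subj <- .window_subjects(windows)
  parts <- split(subj, split)
  for (a in names(parts)) for (b in names(parts)) {
    if (a < b) stopif(length(intersect(parts[[a]], parts[[b]])) > 0,
                      sprintf("subject leakage between %s and %s partitions", a, b))
  }
  test_ix <- which(split == "test")
  trainval_ix <- which(split %in% c("train", "val"))
  tv_subjects <- sort(unique(subj[trainval_ix]))
  if (permute_labels) {
    # negative control: shuffle class labels across training/validation
    # windows, destroying the feature-label association (test labels and
    # windows stay untouched)
    labs <- vapply(windows[trainval_ix], `[[`, integer(1), "action_class")
    labs <- with_seed(derive_seed(tc$seed, "perm"), sample(labs))
    for (k in seq_along(trainval_ix)) {
      windows[[trainval_ix[k]]]$action_class <- labs[k]
    }
  }

  folds <- vector("list", tc$folds)
  fold_groups <- split(tv_subjects,
                       rep_len(seq_len(max(tc$folds, 2L)), length(tv_subjects)))
  for (f in seq_len(tc$folds)) {
    val_subj <- if (tc$folds == 1L) {
      unique(subj[split == "val"])
    } else {
      fold_groups[[f]]
    }
    tr_ix <- trainval_ix[!(subj[trainval_ix] %in% val_subj)]
    va_ix <- trainval_ix[subj[trainval_ix] %in% val_subj]
    folds[[f]] <- .fit_one_fold(windows, tr_ix, va_ix, model_cfg, tc, f,
                                arch_variant, verbose)
  }
  val_acc <- vapply(folds, function(x) x$val_acc, numeric(1))
  out <- list(folds = folds, model_cfg = model_cfg, train_cfg = tc,
              variant = variant,
              test_ix = test_ix,
              summary = data.frame(metric = "val_accuracy",
                                   mean = mean(val_acc),
                                   sd = if (length(val_acc) > 1) stats::sd(val_acc) else NA_real_))
  class(out) <- "motionfuse_fit"
  out
}

#' @export
print.motionfuse_fit <- function(x, ...) {
  cat(sprintf("<motionfuse_fit> %d fold(s), variant %s; val accuracy %.3f",
              length(x$folds), x$variant, x$summary$mean[1]))
  if (!is.na(x$summary$sd[1])) cat(sprintf(" +- %.3f", x$summary$sd[1]))
  cat("\n")
  invisible(x)
}

.fit_one_fold <- function(windows, tr_ix, va_ix, model_cfg, tc, fold,
                          variant, verbose) {
  params <- init_model(model_cfg, seed = derive_seed(tc$seed, "init", fold))
  opt <- adamw_init(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  log <- NULL
  wait <- 0L
  step_seed <- derive_seed(tc$seed, "steps", fold)
  for (epoch in seq_len(tc$epochs)) {
    lr <- cosine_lr(epoch - 1L, tc$epochs, tc$lr_start, tc$lr_end)
    ord <- with_seed(derive_seed(step_seed, epoch), sample(tr_ix))
    batches <- split(ord, ceiling(seq_along(ord) / tc$batch_size))
    ep_loss <- 0
    comp <- c(cls = 0, phase = 0, stab = 0, smooth = 0, unc = 0)
    lag_i <- lag_e <- c(); om <- c(0, 0, 0); omn <- 0
    for (bi in seq_along(batches)) {
      bseed <- derive_seed(step_seed, epoch, bi)
      ws <- lapply(seq_along(batches[[bi]]), function(j)
        .augment_window(windows[[batches[[bi]][j]]], tc, derive_seed(bseed, j)))
      batch <- collate_batch(ws, model_cfg)
      corrupt <- t(vapply(ws, function(w)
        c("imu", "emg") %in% attr(w, "noised"), logical(2)))
      res <- with_seed(derive_seed(bseed, "drop"),
                       model_loss(params, model_cfg, batch, tc$lambdas,
                                  train = TRUE, variant = variant,
                                  corrupt = corrupt))
      st <- adamw_step(params, res$grads, opt, lr = lr,
                       weight_decay = tc$weight_decay)
      params <- st$params; opt <- st$state
      ep_loss <- ep_loss + res$loss
      comp <- comp + res$components
      if (!is.null(res$forward$ai)) {
        lag_i <- c(lag_i, .batch_mean_lag(res$forward$ai$attn,
                                          model_cfg$align$window_radius))
        lag_e <- c(lag_e, .batch_mean_lag(res$forward$ae$attn,
                                          model_cfg$align$window_radius))
      }
      if (!is.null(res$forward$fus)) {
        om <- om + colMeans(res$forward$fus$omega); omn <- omn + 1
      }
    }
    nb <- length(batches)
    va <- .evaluate_loss(params, model_cfg, windows[va_ix], tc, variant = variant)
    row <- data.frame(fold = fold, epoch = epoch, lr = lr,
                      train_loss = ep_loss / nb, val_loss = va$loss,
                      val_acc = va$acc,
                      lag_i = if (length(lag_i)) mean(lag_i) else NA_real_,
                      lag_e = if (length(lag_e)) mean(lag_e) else NA_real_,
                      omega_s = if (omn) om[1] / omn else NA_real_,
                      omega_i = if (omn) om[2] / omn else NA_real_,
                      omega_e = if (omn) om[3] / omn else NA_real_)
    log <- rbind(log, row)
    if (verbose) {
      message(sprintf("fold %d epoch %3d lr %.2e train %.4f val %.4f acc %.3f",
                      fold, epoch, lr, row$train_loss, row$val_loss, row$val_acc))
    }
    if (va$loss < best$loss - 1e-6) {
      best <- list(loss = va$loss, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= tc$patience) break
    }
  }
  list(params = best$params, log = log, best_epoch = best$epoch,
       val_loss = best$loss,
       val_acc = log$val_acc[log$epoch == best$epoch][1], variant = variant)
}

# Clean-forward loss/accuracy on a window set (no augmentation/dropout).
.evaluate_loss <- function(params, model_cfg, windows, tc, variant = "full",
                           batch_size = 64L) {
  if (length(windows) == 0) return(list(loss = NA_real_, acc = NA_real_))
  idx <- split(seq_along(windows), ceiling(seq_along(windows) / batch_size))
  tot <- 0; correct <- 0
  for (ib in idx) {
    batch <- collate_batch(windows[ib], model_cfg)
    res <- model_loss(params, model_cfg, batch, tc$lambdas, train = FALSE,
                      variant = variant)
    tot <- tot + res$loss * length(ib)
    correct <- correct + sum(max.col(res$forward$class_probs, ties.method = "first") == batch$class)
  }
  list(loss = tot / length(windows), acc = correct / length(windows))
}
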