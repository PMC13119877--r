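# Multi-task heads, joint loss, modality dropout and training protocol
# bookkeeping.

test_that("zero features with zero heads give uniform and mid-scale outputs", {
  heads <- list(class = list(W = matrix(0, 8, 12), b = numeric(12)),
                phase = list(W = matrix(0, 8, 4), b = numeric(4)),
                stab = list(W = matrix(0, 8, 1), b = 0))
  z <- matrix(0, 10, 8)
  pred <- forward_heads(z, heads)
  expect_equal(pred$class_probs, rep(1 / 12, 12), tolerance = 1e-12)
  expect_equal(pred$stability, 0.5)
  expect_true(all(abs(rowSums(pred$phase_probs) - 1) < 1e-6))
  # random features still give simplex rows
  z2 <- with_seed(1, matrix(rnorm(80), 10, 8))
  heads$phase$W <- with_seed(2, matrix(rnorm(32), 8, 4))
  pred2 <- forward_heads(z2, heads)
  expect_true(all(abs(rowSums(pred2$phase_probs) - 1) < 1e-6))
})

test_that("multitask loss vanishes on perfect predictions and decomposes linearly", {
  T <- 6L
  pred <- list(class_probs = c(1, 0, 0), stability = 0.7,
               phase_probs = diag(3)[c(1, 1, 2, 2, 3, 3), ])
  class(pred) <- "prediction_bundle"
  labels <- list(class = 1L, phase = c(1L, 1L, 2L, 2L, 3L, 3L), stability = 0.7)
  z <- matrix(2, T, 4)
  out <- multitask_loss(pred, labels, z)
  expect_lt(out$total, 1e-10)
  # uniform class prediction: CE = ln 12
  predu <- list(class_probs = rep(1 / 12, 12), stability = 0.5,
                phase_probs = matrix(1 / 4, T, 4))
  labelsu <- list(class = 3L, phase = rep(2L, T), stability = 0.5)
  outu <- multitask_loss(predu, labelsu, z)
  expect_equal(unname(outu$components["cls"]), log(12), tolerance = 1e-9)
  # doubling lambda_phase doubles exactly the phase component
  w1 <- list(cls = 1, phase = 1, stab = 0.5, smooth = 0.01)
  w2 <- list(cls = 1, phase = 2, stab = 0.5, smooth = 0.01)
  l1 <- multitask_loss(predu, labelsu, z, w1)
  l2 <- multitask_loss(predu, labelsu, z, w2)
  expect_equal(l2$total - l1$total, unname(l1$components["phase"]),
               tolerance = 1e-12)
  expect_error(multitask_loss(predu, list(class = 99L, phase = rep(1L, T),
                                          stability = 0.5), z),
               "out of range")
})

test_that("modality dropout respects p = 0, p = 1 and its empirical rate", {
  w <- tiny_window(1)
  # p = 0: identity
  w0 <- apply_modality_dropout(w, 0, seed = 1)
  attr(w0, "dropped") <- NULL
  expect_equal(w0, w)
  # p = 1 with the survivor rule: exactly one modality retained
  kept <- character(0)
  for (s in 1:30) {
    w1 <- apply_modality_dropout(w, 1, seed = s)
    dropped <- attr(w1, "dropped")
    expect_length(dropped, 2L)
    kept <- c(kept, setdiff(c("skeleton", "imu", "emg"), dropped))
  }
  expect_setequal(unique(kept), c("skeleton", "imu", "emg"))
  # empirical drop frequency at p = 0.2 within 0.2 +- 0.02 per modality
  # (marginal frequency before the survivor-resampling correction is logged
  # through the dropped attribute)
  n <- 10000L
  counts <- c(skeleton = 0, imu = 0, emg = 0)
  for (s in seq_len(n)) {
    d <- attr(apply_modality_dropout(w, 0.2, seed = s), "dropped")
    counts[d] <- counts[d] + 1
  }
  expect_true(all(abs(counts / n - 0.2) < 0.02))
  expect_error(apply_modality_dropout(w, 1.2, seed = 1), "\\[0, 1\\]")
  # dropped modalities are zeroed with cleared masks
  w2 <- apply_modality_dropout(w, 1, seed = 4, include_skeleton = FALSE)
  expect_true(all(w2$imu == 0) && !any(w2$masks$imu))
  expect_true(all(w2$emg == 0) && !any(w2$masks$emg))
  expect_true(any(w2$masks$skeleton))
})

test_that("training with all-zero loss weights leaves parameters unchanged", {
  cfg <- tiny_model_config_dims()
  wins <- lapply(1:8, tiny_window)
  for (i in seq_along(wins)) {
    wins[[i]]$subject_id <- c("A", "A", "A", "B", "A", "A", "A", "C")[i]
  }
  data <- list(windows = wins,
               split = c("train", "train", "train", "val", "train", "train",
                         "train", "test"))
  # weight decay off too: decoupled AdamW decay moves weights even at an
  # identically zero gradient
  tc <- desk_train_config(epochs = 1L, batch_size = 4L, folds = 1L,
                          modality_dropout_p = 0, noise_aug_p = 0,
                          weight_decay = 0,
                          lambdas = list(cls = 0, phase = 0, stab = 0, smooth = 0),
                          seed = 2)
  f <- fit(data, cfg, tc)
  p0 <- init_model(cfg, seed = derive_seed(2L, "init", 1L))
  expect_equal(f$folds[[1]]$params, p0, tolerance = 1e-12)
})

test_that("subject leakage across partitions aborts training", {
  cfg <- tiny_model_config_dims()
  wins <- lapply(1:4, tiny_window)
  for (i in 1:4) wins[[i]]$subject_id <- "A"
  data <- list(windows = wins, split = c("train", "train", "val", "test"))
  expect_error(fit(data, cfg, desk_train_config(epochs = 1L)), "leakage")
})

test_that("a tiny model overfits a small window set (capacity sanity check)", {
  cfg <- tiny_model_config_dims()
  wins <- lapply(1:16, function(s) tiny_window(s))
  for (i in seq_along(wins)) {
    wins[[i]]$subject_id <- "A"
    wins[[i]]$action_class <- as.integer((i - 1) %% 4 + 1)
  }
  params <- init_model(cfg, seed = 1)
  opt <- adamw_init(params)
  batch <- collate_batch(wins, cfg)
  lam <- list(cls = 1, phase = 1, stab = 1, smooth = 0)
  loss <- NA
  for (step in 1:200) {
    res <- model_loss(params, cfg, batch, lam)
    st <- adamw_step(params, res$grads, opt, lr = 3e-3, weight_decay = 0)
    params <- st$params; opt <- st$state
    loss <- res$loss
    if (loss < 0.01) break
  }
  final <- model_loss(params, cfg, batch, lam)
  expect_equal(mean(max.col(final$forward$class_probs) == batch$class), 1)
  expect_lt(final$loss, 0.01)
})

test_that("loss decreases over the first epochs of real training", {
  dat <- small_train_data()
  cfg <- desk_model_config(d_model = 32L, n_classes = 4L,
                           skeleton = list(layers = 1L, heads = 2L, ffn = 64L),
                           imu = list(layers = 1L, hidden = 16L),
                           backbone = list(layers = 1L, heads = 2L, ffn = 64L))
  f <- fit(dat, cfg, desk_train_config(epochs = 6L, batch_size = 40L, seed = 3))
  log <- f$folds[[1]]$log
  expect_lt(log$train_loss[6], log$train_loss[1])
  expect_gt(tail(log$val_acc, 1), 0.5)
  # the per-epoch log carries the alignment and fusion observables
  expect_true(all(c("lag_i", "lag_e", "omega_s", "omega_i", "omega_e") %in%
                    names(log)))
  expect_true(all(is.finite(log$omega_s + log$omega_i + log$omega_e)))
})

test_that("k-fold training yields one checkpoint per fold plus a summary", {
  dat <- small_train_data()
  cfg <- desk_model_config(d_model = 16L, n_classes = 4L,
                           skeleton = list(layers = 1L, heads = 2L, ffn = 32L),
                           imu = list(layers = 1L, hidden = 8L),
                           backbone = list(layers = 1L, heads = 2L, ffn = 32L))
  f <- fit(dat, cfg, desk_train_config(epochs = 2L, batch_size = 48L,
                                       folds = 3L, seed = 4))
  expect_length(f$folds, 3)
  expect_true(all(c("mean", "sd") %in% names(f$summary)))
  expect_false(is.na(f$summary$sd[1]))
  # fold validation subjects rotate
  expect_false(identical(f$folds[[1]]$params, f$folds[[2]]$params))
})
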