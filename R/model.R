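# End-to-end model: three encoders -> cross-modal alignment (vision anchor)
# -> interleaved transformer backbone -> uncertainty-aware fusion ->
# multi-task heads. Forward and backward are wired explicitly; every stage's
# gradients are finite-difference checked in the test suite.

#' Full model configuration
#'
#' Bundles the per-stage configurations around a shared embedding width and
#' token rate. Defaults follow the reference architecture (4-layer/8-head
#' skeleton transformer and backbone with d_model 256 and FFN 1024, 2-layer
#' 128-unit bidirectional LSTM, TCN dilations 1/2/4/8, 4 cross-attention
#' heads, modality dropout 0.2); [desk_model_config()] gives a light preset
#' for CPU-scale experiments.
#'
#' @param d_model Shared latent width.
#' @param token_rate Token rate in Hz.
#' @param window_seconds Window length the model is built for.
#' @param n_classes,phase_count,n_joints,imu_channels,emg_channels Data
#'   dimensions.
#' @param skeleton,imu,emg Encoder stage settings (see [encoder_config()]).
#' @param align Alignment settings: `window_radius`, `heads`, `layers`.
#' @param backbone Backbone settings: `layers`, `heads`, `ffn`.
#' @param fusion_hidden Bottleneck width of the uncertainty heads.
#' @param dropout Dropout rate during training.
#' @param shift_values Alignment value-gathering variant (see
#'   [alignment_config()]).
#' @return A `model_config`.
#' @export
model_config <- function(d_model = 256L, token_rate = 25, window_seconds = 4,
                         n_classes = 12L, phase_count = 4L, n_joints = 17L,
                         imu_channels = 9L, emg_channels = 8L,
                         skeleton = list(layers = 4L, heads = 8L, ffn = 1024L),
                         imu = list(layers = 2L, hidden = 128L),
                         emg = list(kernel = 3L, dilations = c(1L, 2L, 4L, 8L)),
                         align = list(window_radius = 8L, heads = 4L, layers = 2L),
                         backbone = list(layers = 4L, heads = 8L, ffn = 1024L),
                         fusion_hidden = 32L, dropout = 0.1,
                         shift_values = FALSE) {
  T_tokens <- round(window_seconds * token_rate)
  enc <- encoder_config(d_model = d_model, token_rate = token_rate,
                        skeleton = skeleton, imu = imu, emg = emg,
                        dropout = dropout)
  al <- alignment_config(window_radius = align$window_radius, heads = align$heads,
                         layers = align$layers, d_model = d_model,
                         relpos_span = as.integer(align$window_radius +
                                                    max(8L, align$window_radius)),
                         shift_values = shift_values)
  bb <- backbone_config(layers = backbone$layers, heads = backbone$heads,
                        d_model = d_model, ffn = backbone$ffn, dropout = dropout,
                        max_lag = T_tokens)
  cfg <- list(d_model = as.integer(d_model), token_rate = token_rate,
              window_seconds = window_seconds, T_tokens = as.integer(T_tokens),
              n_classes = as.integer(n_classes), phase_count = as.integer(phase_count),
              n_joints = as.integer(n_joints), imu_channels = as.integer(imu_channels),
              emg_channels = as.integer(emg_channels),
              enc = enc, align = al, backbone = bb,
              fusion_hidden = as.integer(fusion_hidden), dropout = dropout)
  class(cfg) <- "model_config"
  cfg
}

#' Desk-scale model preset
#'
#' A configuration small enough to train end-to-end on one CPU in minutes
#' while preserving every architectural element: d_model 64, token rate
#' 8 Hz over 2 s windows (16 tokens), 2-layer/4-head skeleton transformer
#' and backbone, 2x32-unit BiLSTM, TCN dilations 1/2/4, 1 alignment layer.
#'
#' @param ... Overrides forwarded to [model_config()].
#' @return A `model_config`.
#' @export
desk_model_config <- function(...) {
  args <- list(...)
  defaults <- list(d_model = 64L, token_rate = 8, window_seconds = 2,
                   skeleton = list(layers = 2L, heads = 4L, ffn = 128L),
                   imu = list(layers = 2L, hidden = 32L),
                   emg = list(kernel = 3L, dilations = c(1L, 2L, 4L)),
                   align = list(window_radius = 4L, heads = 2L, layers = 1L),
                   backbone = list(layers = 2L, heads = 4L, ffn = 128L),
                   fusion_hidden = 16L)
  defaults[names(args)] <- args
  do.call(model_config, defaults)
}

#' Initialize all model parameters
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed (fully determines the initialization).
#' @return Nested parameter list (encoders, two alignment states, modality
#'   embeddings, backbone, fusion heads, task heads). Task heads are
#'   zero-initialized so an untrained model predicts the uniform
#'   distribution.
#' @export
init_model <- function(cfg, seed = 1L) {
  with_seed(seed, {
    enc <- init_encoders(cfg$enc, cfg$n_joints, cfg$imu_channels, cfg$emg_channels)
    p <- list(
      enc_s = enc$enc_s, enc_i = enc$enc_i, enc_e = enc$enc_e,
      align_i = init_alignment_state(cfg$align),
      align_e = init_alignment_state(cfg$align),
      mod_emb = matrix(stats::rnorm(3 * cfg$d_model, sd = 0.02), 3, cfg$d_model),
      concat_proj = nn_init_linear(3L * cfg$d_model, cfg$d_model),
      backbone = init_backbone(cfg$backbone, cfg$T_tokens),
      fusion = list(s = init_uncertainty_head(cfg$d_model, cfg$fusion_hidden),
                    i = init_uncertainty_head(cfg$d_model, cfg$fusion_hidden),
                    e = init_uncertainty_head(cfg$d_model, cfg$fusion_hidden)),
      heads = list(class = list(W = matrix(0, cfg$d_model, cfg$n_classes),
                                b = numeric(cfg$n_classes)),
                   phase = list(W = matrix(0, cfg$d_model, cfg$phase_count),
                                b = numeric(cfg$phase_count)),
                   stab = list(W = matrix(0, cfg$d_model, 1), b = 0)))
    p
  })
}

# Stack a list of windows into batch-major input matrices and label vectors.
collate_batch <- function(windows, cfg) {
  B <- length(windows)
  Tg <- nrow(windows[[1]]$imu)
  r <- .pool_factor(Tg, windows[[1]]$grid_rate, cfg$token_rate)
  Tt <- Tg %/% r
  sk <- do.call(rbind, lapply(windows, skeleton_input))
  imu <- do.call(rbind, lapply(windows, `[[`, "imu"))
  emg <- do.call(rbind, lapply(windows, `[[`, "emg"))
  tv <- function(get) {
    unlist(lapply(windows, function(w) token_validity(get(w), 1L, Tg, r)))
  }
  tok_center <- ceiling((seq_len(Tt) - 0.5) * r)
  phase_tok <- unlist(lapply(windows, function(w) w$phase[tok_center]))
  list(B = B, Tg = Tg, Tt = Tt, r = r, sk = sk, imu = imu, emg = emg,
       tv_s = tv(function(w) rowSums(w$masks$skeleton) > 0),
       tv_i = tv(function(w) w$masks$imu),
       tv_e = tv(function(w) w$masks$emg),
       class = vapply(windows, `[[`, integer(1), "action_class"),
       phase_tok = as.integer(phase_tok),
       stab = vapply(windows, `[[`, numeric(1), "stability"))
}

# Interleave batched (batch-major) per-modality matrices: window b, token t,
# modality m lands at row (b-1)*3T + 3*(t-1) + m.
.interleave_rows <- function(B, T) {
  base <- rep((seq_len(B) - 1L) * 3L * T, each = T) + 3L * (rep(seq_len(T), B) - 1L)
  list(s = base + 1L, i = base + 2L, e = base + 3L)
}

# Model variants used by the ablation harness:
#   full         - complete architecture
#   no_align     - alignment attention bypassed (sensor tokens pass through
#                  on the shared grid; interpolation-only alignment)
#   concat       - no alignment and no interleaving: channel-wise
#                  concatenation projected to d, single-stream backbone,
#                  fusion bypassed
#   no_backbone  - backbone identity (aligned per-modality streams go
#                  straight to fusion)
#   no_fusion    - uncertainty weighting replaced by the uniform average
model_forward <- function(params, cfg, batch, train = FALSE,
                          variant = "full") {
  B <- batch$B; Tg <- batch$Tg; Tt <- batch$Tt; r <- batch$r
  fs <- enc_s_fwd(batch$sk, params$enc_s, cfg$enc, B, Tg, r, train = train)
  fi <- enc_i_fwd(batch$imu, params$enc_i, cfg$enc, B, Tg, r, train = train)
  fe <- enc_e_fwd(batch$emg, params$enc_e, cfg$enc, B, Tg, r, train = train)
  ai <- ae <- NULL
  if (variant %in% c("full", "no_backbone", "no_fusion")) {
    ai <- align_fwd(fs$Y, fi$Y, params$align_i, cfg$align, B, Tt,
                    key_valid = batch$tv_i)
    ae <- align_fwd(fs$Y, fe$Y, params$align_e, cfg$align, B, Tt,
                    key_valid = batch$tv_e)
    fhat_i <- ai$Y; fhat_e <- ae$Y
  } else {
    fhat_i <- fi$Y; fhat_e <- fe$Y
  }
  ir <- .interleave_rows(B, Tt)
  if (variant == "concat") {
    # direct feature concatenation, no temporal alignment structure
    Xcat <- cbind(fs$Y, fhat_i, fhat_e)
    cp <- nn_linear_fwd(Xcat, params$concat_proj)
    bb <- backbone_fwd(cp$Y, params$backbone, cfg$backbone, B, Tt,
                       train = train, n_mod = 1L)
    z <- bb$Y
    fus <- NULL
    hs <- hi <- he <- NULL
  } else {
    Xint <- matrix(0, B * 3L * Tt, cfg$d_model)
    Xint[ir$s, ] <- fs$Y; Xint[ir$i, ] <- fhat_i; Xint[ir$e, ] <- fhat_e
    Xint <- Xint + params$mod_emb[rep(1:3, B * Tt), , drop = FALSE]
    kv <- logical(B * 3L * Tt)
    kv[ir$s] <- batch$tv_s; kv[ir$i] <- batch$tv_i; kv[ir$e] <- batch$tv_e
    if (variant == "no_backbone") {
      bb <- NULL
      hs <- fs$Y; hi <- fhat_i; he <- fhat_e
    } else {
      bb <- backbone_fwd(Xint, params$backbone, cfg$backbone, B, Tt,
                         key_valid = if (all(kv)) NULL else kv, train = train)
      hs <- bb$Y[ir$s, , drop = FALSE]
      hi <- bb$Y[ir$i, , drop = FALSE]
      he <- bb$Y[ir$e, , drop = FALSE]
    }
    valid <- list(batch$tv_s, batch$tv_i, batch$tv_e)
    if (variant == "no_fusion") {
      # uniform averaging: omega fixed at (1/3, 1/3, 1/3) regardless of
      # stream validity (removing the module removes its invalidity handling)
      omega <- matrix(1 / 3, length(batch$tv_s), 3)
      z <- (hs + hi + he) / 3
      fus <- list(z = z, omega = omega, uniform = TRUE)
    } else {
      fus <- fusion_fwd(hs, hi, he, params$fusion, valid = valid)
      z <- fus$z
    }
  }
  group_b <- rep(seq_len(B), each = Tt)
  pool <- rowsum(z, group_b) / Tt
  cl <- add_row_vec(pool %*% params$heads$class$W, params$heads$class$b)
  class_probs <- softmax_rows(cl)
  ph <- add_row_vec(z %*% params$heads$phase$W, params$heads$phase$b)
  phase_probs <- softmax_rows(ph)
  sb <- as.numeric(pool %*% params$heads$stab$W) + params$heads$stab$b
  stability <- stats::plogis(sb)
  list(fs = fs, fi = fi, fe = fe, ai = ai, ae = ae, bb = bb, fus = fus,
       z = z, pool = pool, group_b = group_b, ir = ir,
       class_probs = class_probs, phase_probs = phase_probs,
       stability = stability, hs = hs, hi = hi, he = he, variant = variant)
}

# Loss + gradients for one batch. Returns total loss, per-component values
# and the full parameter-gradient tree.
model_loss <- function(params, cfg, batch, lambdas, train = FALSE,
                       variant = "full", corrupt = NULL) {
  fw <- model_forward(params, cfg, batch, train = train, variant = variant)
  B <- batch$B; Tt <- batch$Tt
  n <- B * Tt
  eps <- 1e-12
  # components
  p_cls <- fw$class_probs[cbind(seq_len(B), batch$class)]
  loss_cls <- -mean(log(p_cls + eps))
  p_ph <- fw$phase_probs[cbind(seq_len(n), batch$phase_tok)]
  loss_ph <- -mean(log(p_ph + eps))
  loss_st <- mean((fw$stability - batch$stab)^2)
  loss_sm <- smoothness_fwd(fw$z, B, Tt)
  # uncertainty calibration: a training window whose sensor stream was
  # synthetically corrupted must score a higher mean uncertainty u than its
  # clean modalities (margin loss); the end-task loss alone gives the
  # uncertainty heads almost no gradient because the backbone has already
  # mixed the streams
  lam_unc <- lambdas$unc %||% 0
  loss_unc <- 0
  du_extra <- NULL
  if (lam_unc > 0 && !is.null(corrupt) && any(corrupt) &&
      !is.null(fw$fus[["u"]])) {
    ub <- rowsum(fw$fus[["u"]], fw$group_b) / Tt  # B x 3 mean scores
    cmat <- cbind(FALSE, corrupt)               # skeleton never noise-corrupted
    margin <- 1
    dub <- matrix(0, B, 3)
    n_pairs <- 0
    for (b in seq_len(B)) {
      bad <- which(cmat[b, ]); good <- which(!cmat[b, ])
      for (m in bad) for (mp in good) {
        gap <- margin - (ub[b, m] - ub[b, mp])
        loss_unc <- loss_unc + softplus(gap)
        s <- stats::plogis(gap)
        dub[b, m] <- dub[b, m] - s
        dub[b, mp] <- dub[b, mp] + s
        n_pairs <- n_pairs + 1
      }
    }
    if (n_pairs > 0) {
      loss_unc <- as.numeric(loss_unc) / n_pairs
      du_extra <- (lam_unc / n_pairs / Tt) * dub[fw$group_b, , drop = FALSE]
    }
  }
  total <- lambdas$cls * loss_cls + lambdas$phase * loss_ph +
    lambdas$stab * loss_st + lambdas$smooth * loss_sm + lam_unc * loss_unc

  # head gradients
  dcl <- fw$class_probs
  dcl[cbind(seq_len(B), batch$class)] <- dcl[cbind(seq_len(B), batch$class)] - 1
  dcl <- dcl * (lambdas$cls / B)
  dph <- fw$phase_probs
  dph[cbind(seq_len(n), batch$phase_tok)] <- dph[cbind(seq_len(n), batch$phase_tok)] - 1
  dph <- dph * (lambdas$phase / n)
  dsb <- lambdas$stab * 2 * (fw$stability - batch$stab) / B *
    fw$stability * (1 - fw$stability)

  g_heads <- list(class = list(W = crossprod(fw$pool, dcl), b = colSums(dcl)),
                  phase = list(W = crossprod(fw$z, dph), b = colSums(dph)),
                  stab = list(W = crossprod(fw$pool, matrix(dsb, ncol = 1)),
                              b = sum(dsb)))
  dpool <- dcl %*% t(params$heads$class$W) +
    outer(dsb, as.numeric(params$heads$stab$W))
  dz <- dph %*% t(params$heads$phase$W) + dpool[fw$group_b, , drop = FALSE] / Tt
  if (lambdas$smooth != 0) dz <- dz + lambdas$smooth * smoothness_bwd(fw$z, B, Tt)

  g <- model_backward(dz, fw, params, cfg, batch, variant = variant,
                      du_extra = du_extra)
  g$heads <- g_heads
  list(loss = total,
       components = c(cls = loss_cls, phase = loss_ph, stab = loss_st,
                      smooth = loss_sm, unc = loss_unc),
       grads = g, forward = fw)
}

model_backward <- function(dz, fw, params, cfg, batch, variant = "full",
                           du_extra = NULL) {
  B <- batch$B; Tg <- batch$Tg; Tt <- batch$Tt
  ir <- fw$ir
  g <- list()
  if (variant == "concat") {
    bwb <- backbone_bwd(dz, fw$bb, params$backbone, cfg$backbone, B, Tt,
                        n_mod = 1L)
    g$backbone <- bwb$g
    d <- cfg$d_model
    bcp <- nn_linear_bwd(bwb$dX, list(X = cbind(fw$fs$Y, fw$fi$Y, fw$fe$Y)),
                         params$concat_proj)
    g$concat_proj <- bcp$g
    dfs <- bcp$dX[, 1:d, drop = FALSE]
    dfi <- bcp$dX[, (d + 1):(2 * d), drop = FALSE]
    dfe <- bcp$dX[, (2 * d + 1):(3 * d), drop = FALSE]
  } else {
    if (!is.null(fw$fus$uniform)) {
      om <- fw$fus$omega
      dhs <- om[, 1] * dz; dhi <- om[, 2] * dz; dhe <- om[, 3] * dz
      g$fusion <- zero_like(params$fusion)
    } else {
      bf <- fusion_bwd(dz, fw$fus, params$fusion, du_extra = du_extra)
      dhs <- bf$dhs; dhi <- bf$dhi; dhe <- bf$dhe
      g$fusion <- bf$g
    }
    if (variant == "no_backbone") {
      g$backbone <- zero_like(params$backbone)
      dfs <- dhs; dfhat_i <- dhi; dfhat_e <- dhe
      dXint <- NULL
    } else {
      dtok <- matrix(0, B * 3L * Tt, cfg$d_model)
      dtok[ir$s, ] <- dhs; dtok[ir$i, ] <- dhi; dtok[ir$e, ] <- dhe
      bwb <- backbone_bwd(dtok, fw$bb, params$backbone, cfg$backbone, B, Tt)
      g$backbone <- bwb$g
      dXint <- bwb$dX
      g$mod_emb <- rbind(colSums(dXint[ir$s, , drop = FALSE]),
                         colSums(dXint[ir$i, , drop = FALSE]),
                         colSums(dXint[ir$e, , drop = FALSE]))
      dfs <- dXint[ir$s, , drop = FALSE]
      dfhat_i <- dXint[ir$i, , drop = FALSE]
      dfhat_e <- dXint[ir$e, , drop = FALSE]
    }
    if (is.null(g$mod_emb)) g$mod_emb <- matrix(0, 3, cfg$d_model)
    if (variant %in% c("full", "no_backbone", "no_fusion")) {
      bai <- align_bwd(dfhat_i, fw$ai, params$align_i, cfg$align, B, Tt, fw$fs$Y)
      bae <- align_bwd(dfhat_e, fw$ae, params$align_e, cfg$align, B, Tt, fw$fs$Y)
      g$align_i <- bai$g; g$align_e <- bae$g
      dfs <- dfs + bai$dFS + bae$dFS
      dfi <- bai$dFM; dfe <- bae$dFM
    } else {
      g$align_i <- zero_like(params$align_i)
      g$align_e <- zero_like(params$align_e)
      dfi <- dfhat_i; dfe <- dfhat_e
    }
  }
  bs <- enc_s_bwd(dfs, fw$fs, params$enc_s, cfg$enc, B, Tg)
  bi <- enc_i_bwd(dfi, fw$fi, params$enc_i, cfg$enc, B, Tg)
  be <- enc_e_bwd(dfe, fw$fe, params$enc_e, cfg$enc, B, Tg)
  g$enc_s <- bs$g; g$enc_i <- bi$g; g$enc_e <- be$g
  g
}

#' Multi-task prediction heads
#'
#' Class head: mean pool over time, linear map, softmax over the action
#' classes. Phase head: per-token linear map and softmax. Stability head:
#' mean pool, linear map, sigmoid.
#'
#' @param z `[T, d]` fused representation of one window.
#' @param params Model parameter tree (its `$heads` entry is used) or a
#'   bare `heads` list.
#' @return A `prediction_bundle`: `class_probs` (simplex vector),
#'   `phase_probs` (`[T, P]`, simplex rows), `stability` in `[0, 1]`.
#' @export
forward_heads <- function(z, params) {
  z <- as.matrix(z)
  stopif(any(!is.finite(z)), "z must be finite")
  h <- params$heads %||% params
  stopif(nrow(h$class$W) != ncol(z), "feature width does not match heads")
  pool <- colMeans(z)
  cl <- as.numeric(pool %*% h$class$W) + h$class$b
  cl <- exp(cl - max(cl)); cl <- cl / sum(cl)
  ph <- softmax_rows(add_row_vec(z %*% h$phase$W, h$phase$b))
  st <- stats::plogis(sum(pool * h$stab$W) + h$stab$b)
  out <- list(class_probs = cl, phase_probs = ph, stability = st)
  class(out) <- "prediction_bundle"
  out
}

#' Joint multi-task loss
#'
#' `lambda_cls * CE(class) + lambda_phase * mean CE(phase) + lambda_stab *
#' (s - s*)^2 + lambda_smooth * L_smooth(z)`, reported with its component
#' breakdown.
#'
#' @param pred A `prediction_bundle` from [forward_heads()].
#' @param labels `list(class=, phase=, stability=)` ground truth (phase is a
#'   length-`T` integer vector).
#' @param z The fused `[T, d]` sequence entering the smoothness term.
#' @param weights `list(cls=, phase=, stab=, smooth=)` loss weights.
#' @return `list(total=, components=)`.
#' @export
multitask_loss <- function(pred, labels, z,
                           weights = list(cls = 1, phase = 1, stab = 0.5,
                                          smooth = 0.01)) {
  C <- length(pred$class_probs)
  stopif(labels$class < 1 || labels$class > C, "class label out of range")
  stopif(any(labels$phase < 1) || any(labels$phase > ncol(pred$phase_probs)),
         "phase label out of range")
  eps <- 1e-12
  cls <- -log(pred$class_probs[labels$class] + eps)
  ph <- -mean(log(pred$phase_probs[cbind(seq_along(labels$phase), labels$phase)] + eps))
  st <- (pred$stability - labels$stability)^2
  sm <- if (nrow(as.matrix(z)) >= 2) smoothness_penalty(z) else 0
  total <- weights$cls * cls + weights$phase * ph + weights$stab * st +
    weights$smooth * sm
  list(total = total, components = c(cls = cls, phase = ph, stab = st, smooth = sm))
}

#' Training-time modality dropout
#'
#' Zeroes whole modality streams (clearing their validity masks) with
#' probability `p` each, independently, forcing the model to exploit
#' cross-modal redundancy. At least one modality always survives: draws are
#' resampled otherwise (at `p = 1` this degenerates to retaining exactly one
#' uniformly chosen modality).
#'
#' @param window A `unified_window`.
#' @param p Drop probability per modality.
#' @param seed Integer seed.
#' @param include_skeleton Drop the visual anchor too (default `TRUE` for
#'   the standalone op; the training loop excludes the anchor by default
#'   because alignment is vision-anchored).
#' @return The (possibly) modified window, with attribute `"dropped"`
#'   naming the zeroed modalities.
#' @export
apply_modality_dropout <- function(window, p, seed = 1L, include_skeleton = TRUE) {
  stopif(p < 0 || p > 1, "p must be in [0, 1]")
  with_seed(seed, {
    mods <- if (include_skeleton) c("skeleton", "imu", "emg") else c("imu", "emg")
    # resample until a modality survives; at p = 1 the conditional law
    # degenerates to retaining exactly one uniformly chosen modality
    for (i in seq_len(1000)) {
      drop <- stats::runif(length(mods)) < p
      if (!include_skeleton || any(!drop)) break
    }
    if (include_skeleton && all(drop)) drop[sample(length(mods), 1)] <- FALSE
    dropped <- mods[drop]
    for (m in dropped) {
      if (m == "skeleton") {
        window$skeleton[] <- 0
        window$masks$skeleton[] <- FALSE
      } else {
        window[[m]][] <- 0
        window$masks[[m]][] <- FALSE
      }
    }
    attr(window, "dropped") <- dropped
    window
  })
}

# Mean expected lag of a batched alignment forward (interior rows, final
# layer, averaged over heads and windows).
.batch_mean_lag <- function(attn, W) {
  dims <- dim(attn)   # T x T x H x B x L
  T <- dims[1]
  interior <- (W + 1):(T - W)
  if (length(interior) < 1) interior <- seq_len(T)
  kk <- seq_len(T)
  tot <- 0; cnt <- 0
  for (b in seq_len(dims[4])) {
    for (h in seq_len(dims[3])) {
      P <- attn[, , h, b, dims[5]]
      lag <- P %*% kk - seq_len(T)
      tot <- tot + sum(lag[interior]); cnt <- cnt + length(interior)
    }
  }
  tot / cnt
}

#' Run a trained model over windows
#'
#' @param params Model parameters.
#' @param cfg The [model_config()] used at training time.
#' @param windows List of `unified_window`s.
#' @param batch_size Windows per forward batch.
#' @param variant Architecture variant (see [run_ablation()]).
#' @return `list(class_probs=, class_pred=, phase_probs=, phase_pred=,
#'   stability=, omega=, lag_i=, lag_e=)`; `omega` holds per-window mean
#'   fusion weights.
#' @export
model_predict <- function(params, cfg, windows, batch_size = 32L,
                          variant = "full") {
  N <- length(windows)
  C <- cfg$n_classes
  probs <- matrix(0, N, C)
  stab <- numeric(N)
  omega <- matrix(NA_real_, N, 3, dimnames = list(NULL, c("S", "I", "E")))
  phase_probs <- vector("list", N)
  lag_i <- lag_e <- numeric(0)
  idx <- split(seq_len(N), ceiling(seq_len(N) / batch_size))
  for (ib in idx) {
    batch <- collate_batch(windows[ib], cfg)
    fw <- model_forward(params, cfg, batch, train = FALSE, variant = variant)
    probs[ib, ] <- fw$class_probs
    stab[ib] <- fw$stability
    for (j in seq_along(ib)) {
      rows <- ((j - 1) * batch$Tt + 1):(j * batch$Tt)
      phase_probs[[ib[j]]] <- fw$phase_probs[rows, , drop = FALSE]
      if (!is.null(fw$fus)) omega[ib[j], ] <- colMeans(fw$fus$omega[rows, , drop = FALSE])
    }
    if (!is.null(fw$ai)) {
      lag_i <- c(lag_i, .batch_mean_lag(fw$ai$attn, cfg$align$window_radius))
      lag_e <- c(lag_e, .batch_mean_lag(fw$ae$attn, cfg$align$window_radius))
    }
  }
  list(class_probs = probs,
       class_pred = max.col(probs, ties.method = "first"),
       phase_probs = phase_probs,
       phase_pred = lapply(phase_probs, max.col, ties.method = "first"),
       stability = stab, omega = omega,
       lag_i = if (length(lag_i)) mean(lag_i) else NA_real_,
       lag_e = if (length(lag_e)) mean(lag_e) else NA_real_)
}
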