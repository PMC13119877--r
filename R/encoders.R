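# Modality-specific encoders projecting each stream into the shared latent
# space at a common token rate: a temporal transformer for the skeleton, a
# 2-layer bidirectional LSTM for the IMU, and a residual dilated temporal
# convolution stack for the EMG. All three emit [T x d_model] token
# sequences on the same token grid (grid-rate features strided-pooled down
# to the token rate), the precondition for interleaving.

#' Encoder configuration
#'
#' @param d_model Shared embedding width.
#' @param token_rate Model token rate in Hz; all encoders pool their
#'   grid-rate features to this rate, keeping the joint sequence short
#'   enough for the transformer stages.
#' @param skeleton `list(layers=, heads=, ffn=)` for the skeleton temporal
#'   transformer.
#' @param imu `list(layers=, hidden=)` for the bidirectional LSTM (hidden
#'   units per direction).
#' @param emg `list(kernel=, dilations=)` for the dilated temporal
#'   convolution stack.
#' @param dropout Dropout rate used during training.
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(d_model = 256L, token_rate = 25,
                           skeleton = list(layers = 4L, heads = 8L, ffn = 1024L),
                           imu = list(layers = 2L, hidden = 128L),
                           emg = list(kernel = 3L, dilations = c(1L, 2L, 4L, 8L)),
                           dropout = 0.1) {
  stopif(d_model %% skeleton$heads != 0, "skeleton heads must divide d_model")
  stopif(any(diff(emg$dilations) <= 0), "dilations must be strictly increasing")
  cfg <- list(d_model = as.integer(d_model), token_rate = token_rate,
              skeleton = skeleton, imu = imu, emg = emg, dropout = dropout)
  class(cfg) <- "encoder_config"
  cfg
}

init_encoders <- function(cfg, n_joints, imu_channels, emg_channels) {
  d <- cfg$d_model
  list(
    enc_s = list(embed = nn_init_linear(3L * n_joints, d),
                 layers = lapply(seq_len(cfg$skeleton$layers), function(l)
                   nn_init_tf_layer(d, cfg$skeleton$ffn)),
                 lnf = nn_init_layernorm(d)),
    enc_i = list(lstm = nn_init_bilstm(imu_channels, cfg$imu$hidden, cfg$imu$layers),
                 proj = nn_init_linear(2L * cfg$imu$hidden, d)),
    enc_e = list(inp = nn_init_linear(emg_channels, d),
                 blocks = nn_init_tcn(d, cfg$emg$kernel, cfg$emg$dilations),
                 lnf = nn_init_layernorm(d)))
}

# Pool factor between the grid rate and token rate for a window of Tg
# samples mapping to Tt tokens.
.pool_factor <- function(Tg, grid_rate, token_rate) {
  r <- grid_rate / token_rate
  stopif(abs(r - round(r)) > 1e-9, "token_rate must divide grid_rate")
  as.integer(round(r))
}

# Token validity: a token is valid when any grid sample in its span is.
token_validity <- function(valid_grid, B, Tg, r) {
  tv <- nn_pool_fwd(matrix(as.numeric(valid_grid), ncol = 1), B, Tg, r)$Y
  as.numeric(tv) > 0
}

# ---- skeleton: temporal transformer ---------------------------------------

enc_s_fwd <- function(X, p, cfg, B, Tg, r, train = FALSE) {
  stopif(ncol(X) != nrow(p$embed$W), "skeleton input width does not match encoder")
  em <- nn_linear_fwd(X, p$embed)
  pos <- positional_encoding(Tg, cfg$d_model)
  H <- em$Y + pos[rep(seq_len(Tg), B), , drop = FALSE]
  layer_caches <- vector("list", length(p$layers))
  for (l in seq_along(p$layers)) {
    f <- nn_tf_layer_fwd(H, p$layers[[l]], cfg$skeleton$heads, B, Tg,
                         dropout = cfg$dropout, train = train)
    layer_caches[[l]] <- f
    H <- f$Y
  }
  lnf <- nn_layernorm_fwd(H, p$lnf)
  pool <- nn_pool_fwd(lnf$Y, B, Tg, r)
  list(Y = pool$Y, em = em, layer_caches = layer_caches, lnf = lnf, pool = pool)
}

enc_s_bwd <- function(dY, fwd, p, cfg, B, Tg) {
  dH <- nn_pool_bwd(dY, fwd$pool)
  bln <- nn_layernorm_bwd(dH, fwd$lnf, p$lnf)
  dH <- bln$dX
  g_layers <- vector("list", length(p$layers))
  for (l in rev(seq_along(p$layers))) {
    bw <- nn_tf_layer_bwd(dH, fwd$layer_caches[[l]], p$layers[[l]],
                          cfg$skeleton$heads, B, Tg)
    g_layers[[l]] <- bw$g
    dH <- bw$dX
  }
  bem <- nn_linear_bwd(dH, fwd$em, p$embed)
  list(dX = bem$dX, g = list(embed = bem$g, layers = g_layers, lnf = bln$g))
}

# ---- IMU: bidirectional LSTM ----------------------------------------------

enc_i_fwd <- function(X, p, cfg, B, Tg, r, train = FALSE) {
  stopif(any(!is.finite(X)), "non-finite IMU input")
  ls <- nn_bilstm_fwd(X, p$lstm, B, Tg)
  pr <- nn_linear_fwd(ls$Y, p$proj)
  pool <- nn_pool_fwd(pr$Y, B, Tg, r)
  list(Y = pool$Y, ls = ls, pr = pr, pool = pool)
}

enc_i_bwd <- function(dY, fwd, p, cfg, B, Tg) {
  dH <- nn_pool_bwd(dY, fwd$pool)
  bp <- nn_linear_bwd(dH, fwd$pr, p$proj)
  bl <- nn_bilstm_bwd(bp$dX, fwd$ls, p$lstm, B, Tg)
  list(dX = bl$dX, g = list(lstm = bl$g, proj = bp$g))
}

# ---- EMG: dilated temporal convolutions -----------------------------------

enc_e_fwd <- function(X, p, cfg, B, Tg, r, train = FALSE) {
  stopif(any(!is.finite(X)), "non-finite EMG input")
  stopif(Tg < tcn_receptive_field(cfg$emg$kernel, cfg$emg$dilations),
         "window shorter than the receptive field of the convolution stack")
  ip <- nn_linear_fwd(X, p$inp)
  tc <- nn_tcn_fwd(ip$Y, p$blocks, B, Tg, cfg$emg$dilations)
  lnf <- nn_layernorm_fwd(tc$Y, p$lnf)
  pool <- nn_pool_fwd(lnf$Y, B, Tg, r)
  list(Y = pool$Y, ip = ip, tc = tc, lnf = lnf, pool = pool)
}

enc_e_bwd <- function(dY, fwd, p, cfg, B, Tg) {
  dH <- nn_pool_bwd(dY, fwd$pool)
  bln <- nn_layernorm_bwd(dH, fwd$lnf, p$lnf)
  bt <- nn_tcn_bwd(bln$dX, fwd$tc, p$blocks, B, Tg)
  bi <- nn_linear_bwd(bt$dX, fwd$ip, p$inp)
  list(dX = bi$dX, g = list(inp = bi$g, blocks = bt$g, lnf = bln$g))
}

# ---- exported single-window wrappers --------------------------------------

.window_token_count <- function(win, cfg) {
  Tg <- nrow(win$imu)
  r <- .pool_factor(Tg, win$grid_rate, cfg$token_rate)
  list(Tg = Tg, r = r, Tt = Tg %/% r)
}

# Skeleton input channels: flattened (x, y) per joint with masked joints
# zero-filled, plus one validity channel per joint so occlusion is
# observable by the encoder.
skeleton_input <- function(win) {
  Tg <- dim(win$skeleton)[1]
  J <- dim(win$skeleton)[2]
  coords <- matrix(win$skeleton, Tg, 2L * J)   # columns: x_1..x_J, y_1..y_J
  msk <- win$masks$skeleton
  cbind(coords * cbind(msk, msk), msk * 1)
}

#' Encode one window's skeleton stream
#'
#' Flattened joint coordinates (+ per-joint validity channels) are linearly
#' embedded, combined with sinusoidal absolute positions, passed through the
#' pre-norm temporal transformer stack and strided-pooled to the token rate.
#'
#' @param win A `unified_window`.
#' @param cfg An [encoder_config()].
#' @param params Parameter tree from [init_encoders()] (or a model's
#'   `$enc_s`).
#' @return A [token_sequence()] of modality `"S"`.
#' @export
encode_skeleton <- function(win, cfg, params) {
  wt <- .window_token_count(win, cfg)
  p <- params$enc_s %||% params
  f <- enc_s_fwd(skeleton_input(win), p, cfg, 1L, wt$Tg, wt$r)
  token_sequence(f$Y, "S", cfg$token_rate,
                 token_validity(rowSums(win$masks$skeleton) > 0, 1L, wt$Tg, wt$r))
}

#' Encode one window's IMU stream
#'
#' Two bidirectional LSTM layers (hidden states of both directions
#' concatenated), a linear projection to `d_model`, and strided pooling to
#' the token rate.
#'
#' @inheritParams encode_skeleton
#' @return A [token_sequence()] of modality `"I"`.
#' @export
encode_imu <- function(win, cfg, params) {
  wt <- .window_token_count(win, cfg)
  p <- params$enc_i %||% params
  f <- enc_i_fwd(win$imu, p, cfg, 1L, wt$Tg, wt$r)
  token_sequence(f$Y, "I", cfg$token_rate,
                 token_validity(win$masks$imu, 1L, wt$Tg, wt$r))
}

#' Encode one window's EMG stream
#'
#' Residual blocks of two non-causal (symmetrically padded) dilated
#' convolutions each, dilation doubling per block, followed by strided
#' pooling to the token rate. Errors if the window is shorter than the
#' stack's receptive field.
#'
#' @inheritParams encode_skeleton
#' @return A [token_sequence()] of modality `"E"`.
#' @export
encode_emg <- function(win, cfg, params) {
  wt <- .window_token_count(win, cfg)
  p <- params$enc_e %||% params
  f <- enc_e_fwd(win$emg, p, cfg, 1L, wt$Tg, wt$r)
  token_sequence(f$Y, "E", cfg$token_rate,
                 token_validity(win$masks$emg, 1L, wt$Tg, wt$r))
}
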