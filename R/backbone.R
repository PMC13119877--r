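# Multimodal temporal transformer backbone: per-modality token sequences are
# interleaved along time (tokens of the three modalities at the same step
# become adjacent), processed by pre-norm self-attention layers whose logits
# carry a relative temporal bias and a 3x3 modality-relation bias, then
# de-interleaved back into per-modality high-level sequences.

#' Backbone configuration
#'
#' @param layers,heads,d_model,ffn Transformer stack dimensions.
#' @param dropout Dropout rate inside attention/FFN sublayers (GELU FFN).
#' @param max_lag Clipping bound for the relative temporal bias table
#'   (defaults to the token count at initialization).
#' @return A `backbone_config` list.
#' @export
backbone_config <- function(layers = 4L, heads = 8L, d_model = 256L,
                            ffn = 1024L, dropout = 0.1, max_lag = NULL) {
  stopif(d_model %% heads != 0, "heads must divide d_model")
  cfg <- list(layers = as.integer(layers), heads = as.integer(heads),
              d_model = as.integer(d_model), ffn = as.integer(ffn),
              dropout = dropout, max_lag = max_lag)
  class(cfg) <- "backbone_config"
  cfg
}

init_backbone <- function(cfg, T_tokens) {
  max_lag <- cfg$max_lag %||% T_tokens
  layers <- lapply(seq_len(cfg$layers), function(l) {
    list(tf = nn_init_tf_layer(cfg$d_model, cfg$ffn),
         b_time = matrix(stats::rnorm(cfg$heads * (2 * max_lag + 1), sd = 0.02),
                         cfg$heads, 2 * max_lag + 1),
         b_modal = matrix(stats::rnorm(cfg$heads * 9, sd = 0.02), cfg$heads, 9))
  })
  list(layers = layers, max_lag = max_lag)
}

#' Interleave per-modality token sequences
#'
#' Forms the joint sequence of length 3T with deterministic S, I, E ordering
#' at every time step, so tokens from different modalities at the same step
#' are locally adjacent.
#'
#' @param f_s,f_hat_i,f_hat_e `[T, d]` matrices or `token_sequence`s of
#'   equal shape.
#' @param modality_embedding Optional `[3, d]` matrix of modality embeddings
#'   added to the corresponding tokens.
#' @return An `interleaved_sequence`: `tokens` (`[3T, d]`), `modality_ids`
#'   (1 = S, 2 = I, 3 = E) and zero-based `time_ids`.
#' @export
interleave <- function(f_s, f_hat_i, f_hat_e, modality_embedding = NULL) {
  get_f <- function(x) if (inherits(x, "token_sequence")) x$features else as.matrix(x)
  get_v <- function(x, T) if (inherits(x, "token_sequence")) x$validity else rep(TRUE, T)
  FS <- get_f(f_s); FI <- get_f(f_hat_i); FE <- get_f(f_hat_e)
  stopif(!all(dim(FS) == dim(FI)) || !all(dim(FS) == dim(FE)),
         "all three sequences must share T and d")
  T <- nrow(FS)
  tokens <- matrix(0, 3 * T, ncol(FS))
  tokens[seq(1, 3 * T, by = 3), ] <- FS
  tokens[seq(2, 3 * T, by = 3), ] <- FI
  tokens[seq(3, 3 * T, by = 3), ] <- FE
  if (!is.null(modality_embedding)) {
    tokens <- tokens + modality_embedding[rep(1:3, T), , drop = FALSE]
  }
  validity <- logical(3 * T)
  validity[seq(1, 3 * T, by = 3)] <- get_v(f_s, T)
  validity[seq(2, 3 * T, by = 3)] <- get_v(f_hat_i, T)
  validity[seq(3, 3 * T, by = 3)] <- get_v(f_hat_e, T)
  out <- list(tokens = tokens, modality_ids = rep(1:3, T),
              time_ids = rep(seq_len(T) - 1L, each = 3L), validity = validity)
  class(out) <- "interleaved_sequence"
  out
}

#' Split an interleaved sequence back into per-modality streams
#'
#' Exact inverse of [interleave()] on untouched tokens: a pure permutation,
#' no mixing across modalities.
#'
#' @param x An `interleaved_sequence`.
#' @return `list(H_S=, H_I=, H_E=)` of `[T, d]` matrices.
#' @export
deinterleave_aggregate <- function(x) {
  stopif(!inherits(x, "interleaved_sequence"), "x must be an interleaved_sequence")
  n <- nrow(x$tokens)
  stopif(n %% 3 != 0 || !all(x$modality_ids == rep(1:3, n / 3)),
         "malformed modality interleaving pattern")
  list(H_S = x$tokens[seq(1, n, by = 3), , drop = FALSE],
       H_I = x$tokens[seq(2, n, by = 3), , drop = FALSE],
       H_E = x$tokens[seq(3, n, by = 3), , drop = FALSE])
}

# Bias lookup indices for an interleaved sequence of T steps: every entry of
# the (3T x 3T) logit matrix reads one relative-time table cell and one
# ordered modality-pair cell.
.backbone_bias_idx <- function(T, max_lag, n_mod = 3L) {
  tid <- rep(seq_len(T) - 1L, each = n_mod)
  mid <- rep(seq_len(n_mod), T)
  dt <- outer(tid, tid, "-")
  dt <- pmin(pmax(dt, -max_lag), max_lag)
  tidx <- dt + max_lag + 1L
  midx <- outer(mid, mid, function(i, j) (i - 1L) * 3L + j)
  list(tidx = tidx, midx = midx)
}

.backbone_bias <- function(lp, idx, heads) {
  T3 <- nrow(idx$tidx)
  bias <- array(0, dim = c(T3, T3, heads))
  for (h in seq_len(heads)) {
    bias[, , h] <- matrix(lp$b_time[h, idx$tidx], T3, T3) +
      matrix(lp$b_modal[h, idx$midx], T3, T3)
  }
  bias
}

.backbone_bias_grad <- function(dbias, idx, heads, n_time, n_modal) {
  d_time <- matrix(0, heads, n_time)
  d_modal <- matrix(0, heads, n_modal)
  for (h in seq_len(heads)) {
    db <- dbias[, , h]
    s <- rowsum(as.numeric(db), as.integer(idx$tidx))
    d_time[h, as.integer(rownames(s))] <- s[, 1]
    s <- rowsum(as.numeric(db), as.integer(idx$midx))
    d_modal[h, as.integer(rownames(s))] <- s[, 1]
  }
  list(b_time = d_time, b_modal = d_modal)
}

#' One backbone encoder layer
#'
#' Pre-norm transformer layer on an interleaved sequence:
#' `U = X + Attn(LN(X))`, `X' = U + FFN(LN(U))`, with attention logits
#' `Q K' / sqrt(d_h) + B_time[t_i - t_j] + B_modal[m_i, m_j]` and row
#' softmax. Invalid tokens are masked as attention keys.
#'
#' @param x An `interleaved_sequence`.
#' @param bias Layer parameters carrying `b_time` / `b_modal` tables (as
#'   produced inside [init_backbone()]); pass tables of zeros for a plain
#'   pre-norm layer.
#' @param cfg A [backbone_config()].
#' @param params The layer's transformer parameters (`$tf` entry of an
#'   [init_backbone()] layer).
#' @return The transformed `interleaved_sequence` with attribute
#'   `"attn"` (`[3T, 3T, heads]` attention maps).
#' @export
encoder_layer <- function(x, bias, cfg, params) {
  stopif(!inherits(x, "interleaved_sequence"), "x must be an interleaved_sequence")
  T3 <- nrow(x$tokens)
  T <- T3 %/% 3L
  max_lag <- (ncol(bias$b_time) - 1L) %/% 2L
  idx <- .backbone_bias_idx(T, max_lag)
  b <- .backbone_bias(bias, idx, cfg$heads)
  kv <- if (all(x$validity)) NULL else x$validity
  fwd <- nn_tf_layer_fwd(x$tokens, params, cfg$heads, B = 1L, T = T3,
                         bias = b, key_valid = kv)
  stopif(any(!is.finite(fwd$Y)), "non-finite activations in backbone layer")
  x$tokens <- fwd$Y
  attn <- fwd$at$P[, , , 1, drop = FALSE]
  dim(attn) <- dim(fwd$at$P)[1:3]
  attr(x, "attn") <- attn
  x
}

# Batched backbone stack used by the model (batch-major (B*3T) x d tokens).
backbone_fwd <- function(Xint, bk, cfg, B, T, key_valid = NULL, train = FALSE,
                         n_mod = 3L) {
  T3 <- n_mod * T
  idx <- .backbone_bias_idx(T, bk$max_lag, n_mod)
  caches <- vector("list", length(bk$layers))
  for (l in seq_along(bk$layers)) {
    b <- .backbone_bias(bk$layers[[l]], idx, cfg$heads)
    fwd <- nn_tf_layer_fwd(Xint, bk$layers[[l]]$tf, cfg$heads, B, T3, bias = b,
                           key_valid = key_valid, dropout = cfg$dropout,
                           train = train)
    caches[[l]] <- fwd
    Xint <- fwd$Y
  }
  list(Y = Xint, caches = caches, idx = idx)
}

backbone_bwd <- function(dY, fwd, bk, cfg, B, T, n_mod = 3L) {
  T3 <- n_mod * T
  g_layers <- vector("list", length(bk$layers))
  for (l in rev(seq_along(bk$layers))) {
    bw <- nn_tf_layer_bwd(dY, fwd$caches[[l]], bk$layers[[l]]$tf, cfg$heads, B,
                          T3, has_bias = TRUE)
    bg <- .backbone_bias_grad(bw$dbias, fwd$idx, cfg$heads,
                              ncol(bk$layers[[l]]$b_time), 9L)
    g_layers[[l]] <- list(tf = bw$g, b_time = bg$b_time, b_modal = bg$b_modal)
    dY <- bw$dX
  }
  list(dX = dY, g = list(layers = g_layers, max_lag = NULL))
}
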