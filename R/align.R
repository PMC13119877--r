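# Cross-modal temporal alignment attention: visual-anchored local attention
# over sensor tokens with a learnable per-modality temporal offset carried
# by a continuous-lag relative position bias.
#
# For anchor queries Q_t and sensor keys K_k inside the temporal
# neighbourhood |t - k| <= W, attention logits are
#     Q_t K_k' / sqrt(d_h) + R(t - k - delta)
# where R is a learnable table over integer lags, evaluated at the
# continuous lag t - k - delta by linear interpolation. The fractional,
# learnable offset delta is therefore differentiable: shifting delta slides
# the bias profile across the neighbourhood, which moves the attention mass
# and hence the expected lag E[k - t] of each attention row. The module
# output per layer is the convex combination sum_k A_{t,k} V_k (heads
# concatenated); stacked layers are joined by residual connections on the
# sensor stream, with the final layer's attention output as the aligned
# feature sequence.

#' Alignment-attention configuration
#'
#' @param window_radius Local neighbourhood half-width W in tokens. The
#'   default of 8 tokens covers plausible neuromuscular latency plus clock
#'   drift at typical token rates.
#' @param heads Cross-attention heads.
#' @param layers Stacked alignment layers.
#' @param d_model Embedding width (must be divisible by `heads`).
#' @param offset_init Initial temporal offset in tokens.
#' @param relpos_span Half-span of the relative-position table; must exceed
#'   `window_radius + max |delta|` so interpolation stays in-table.
#' @param shift_values Also gather values at the fractionally shifted index
#'   (linear interpolation); by default values are taken at integer lags and
#'   the learned bias alone carries the shift.
#' @return An `alignment_config` list.
#' @export
alignment_config <- function(window_radius = 8L, heads = 4L, layers = 2L,
                             d_model = 256L, offset_init = 0,
                             relpos_span = window_radius + 8L,
                             shift_values = FALSE) {
  stopif(window_radius < 0, "window_radius must be >= 0")
  stopif(d_model %% heads != 0, "heads must divide d_model")
  stopif(relpos_span <= window_radius, "relpos_table span must exceed window radius")
  cfg <- list(window_radius = as.integer(window_radius), heads = as.integer(heads),
              layers = as.integer(layers), d_model = as.integer(d_model),
              offset_init = offset_init, relpos_span = as.integer(relpos_span),
              shift_values = isTRUE(shift_values))
  class(cfg) <- "alignment_config"
  cfg
}

#' Initialize learnable alignment state
#'
#' @param cfg An [alignment_config()].
#' @return List with the scalar offset `delta` (token units) and, per layer,
#'   query/key/value projections and a per-head relative-position table.
#' @export
init_alignment_state <- function(cfg) {
  layers <- lapply(seq_len(cfg$layers), function(l) {
    list(q = nn_init_linear(cfg$d_model, cfg$d_model),
         k = nn_init_linear(cfg$d_model, cfg$d_model),
         v = nn_init_linear(cfg$d_model, cfg$d_model),
         relpos = matrix(stats::rnorm(cfg$heads * (2 * cfg$relpos_span + 1), sd = 0.02),
                         cfg$heads, 2 * cfg$relpos_span + 1))
  })
  list(delta = cfg$offset_init, layers = layers)
}

# Interpolated bias profile R(t - k - delta) for one head table (vector over
# lags -span..span). Returns the T x T bias plus interpolation bookkeeping.
.relpos_bias <- function(tab, span, T, delta) {
  delta <- as.numeric(delta)
  lag <- outer(seq_len(T), seq_len(T), "-") - delta   # t - k - delta
  pos <- lag + span + 1
  i0 <- pmin(pmax(floor(pos), 1), length(tab) - 1)
  frac <- pmin(pmax(pos - i0, 0), 1)
  val <- tab[i0] * (1 - frac) + tab[i0 + 1] * frac
  list(val = matrix(val, T, T), i0 = i0, frac = frac)
}

# Forward pass over a batch of windows (batch-major matrices).
align_fwd <- function(FS, FM, state, cfg, B, T, key_valid = NULL) {
  d <- cfg$d_model
  H <- cfg$heads
  dh <- d %/% H
  W <- cfg$window_radius
  scal <- 1 / sqrt(dh)
  band <- abs(outer(seq_len(T), seq_len(T), "-")) <= W
  X <- FM
  caches <- vector("list", cfg$layers)
  Pall <- array(0, dim = c(T, T, H, B, cfg$layers))
  for (l in seq_len(cfg$layers)) {
    lp <- state$layers[[l]]
    Q <- add_row_vec(FS %*% lp$q$W, lp$q$b)
    K <- add_row_vec(X %*% lp$k$W, lp$k$b)
    V <- add_row_vec(X %*% lp$v$W, lp$v$b)
    rb <- lapply(seq_len(H), function(h)
      .relpos_bias(lp$relpos[h, ], cfg$relpos_span, T, state$delta))
    O <- matrix(0, nrow(X), d)
    Vsh <- NULL; shf <- NULL
    if (cfg$shift_values) {
      # interpolated value gathering at fractional index k + delta
      shf <- .value_shift_weights(T, state$delta)
    }
    for (b in seq_len(B)) {
      rows <- ((b - 1) * T + 1):(b * T)
      kv <- if (is.null(key_valid)) NULL else key_valid[rows]
      Vb_full <- V[rows, , drop = FALSE]
      if (cfg$shift_values) Vb_full <- shf$Wm %*% Vb_full
      for (h in seq_len(H)) {
        cols <- ((h - 1) * dh + 1):(h * dh)
        S <- (Q[rows, cols, drop = FALSE] %*% t(K[rows, cols, drop = FALSE])) * scal +
          rb[[h]]$val
        S[!band] <- -1e30
        if (!is.null(kv) && !all(kv)) S[, !kv] <- -1e30
        P <- softmax_rows(S)
        Pall[, , h, b, l] <- P
        O[rows, cols] <- P %*% Vb_full[, cols, drop = FALSE]
      }
    }
    caches[[l]] <- list(Q = Q, K = K, V = V, X = X, rb = rb, O = O, shf = shf)
    if (l < cfg$layers) X <- X + O else X <- O
  }
  list(Y = X, attn = Pall, caches = caches, band = band, key_valid = key_valid)
}

# Linear interpolation weights for shifting a T-length sequence by +delta
# (row t of Wm picks value at index t + delta, clamped at the edges).
.value_shift_weights <- function(T, delta) {
  src <- seq_len(T) + delta
  i0 <- pmin(pmax(floor(src), 1), T - 1)
  frac <- pmin(pmax(src - i0, 0), 1)
  Wm <- matrix(0, T, T)
  Wm[cbind(seq_len(T), i0)] <- 1 - frac
  Wm[cbind(seq_len(T), i0 + 1)] <- Wm[cbind(seq_len(T), i0 + 1)] + frac
  clamped <- (src < 1) | (src > T)
  list(Wm = Wm, i0 = i0, frac = frac, clamped = clamped)
}

# Backward pass. `FS` is the anchor input used in the forward call (queries
# are drawn from it in every layer, so its gradient accumulates across
# layers).
align_bwd <- function(dY, fwd, state, cfg, B, T, FS) {
  d <- cfg$d_model
  H <- cfg$heads
  dh <- d %/% H
  scal <- 1 / sqrt(dh)
  g_layers <- vector("list", cfg$layers)
  d_delta <- 0
  dFS <- matrix(0, nrow(dY), d)
  dX_next <- dY
  for (l in rev(seq_len(cfg$layers))) {
    cc <- fwd$caches[[l]]
    lp <- state$layers[[l]]
    dO <- dX_next
    dX <- if (l < cfg$layers) dX_next else matrix(0, nrow(dY), d)
    dQ <- matrix(0, nrow(dY), d); dK <- dQ; dV <- dQ
    dS_sum <- array(0, dim = c(T, T, H))   # summed over the batch, per head
    for (b in seq_len(B)) {
      rows <- ((b - 1) * T + 1):(b * T)
      Vb_full <- cc$V[rows, , drop = FALSE]
      if (cfg$shift_values) Vb_full <- cc$shf$Wm %*% Vb_full
      dVb_sh <- matrix(0, T, d)
      for (h in seq_len(H)) {
        cols <- ((h - 1) * dh + 1):(h * dh)
        P <- fwd$attn[, , h, b, l]
        dOb <- dO[rows, cols, drop = FALSE]
        dP <- dOb %*% t(Vb_full[, cols, drop = FALSE])
        dVb_sh[, cols] <- dVb_sh[, cols] + crossprod(P, dOb)
        dS <- P * (dP - rowSums(P * dP))
        dS_sum[, , h] <- dS_sum[, , h] + dS
        dQ[rows, cols] <- (dS %*% cc$K[rows, cols, drop = FALSE]) * scal
        dK[rows, cols] <- (crossprod(dS, cc$Q[rows, cols, drop = FALSE])) * scal
      }
      if (cfg$shift_values) {
        dV[rows, ] <- dV[rows, ] + crossprod(cc$shf$Wm, dVb_sh)
        ok <- !cc$shf$clamped
        if (any(ok)) {
          Vb <- cc$V[rows, , drop = FALSE]
          dvdd <- Vb[cc$shf$i0 + 1, , drop = FALSE] - Vb[cc$shf$i0, , drop = FALSE]
          d_delta <- d_delta + sum(dVb_sh[ok, , drop = FALSE] * dvdd[ok, , drop = FALSE])
        }
      } else {
        dV[rows, ] <- dV[rows, ] + dVb_sh
      }
    }
    # relpos table + delta gradients (interpolation indices are shared
    # across the batch, so one vectorized scatter per head suffices)
    drel <- matrix(0, nrow(lp$relpos), ncol(lp$relpos))
    for (h in seq_len(H)) {
      rb <- cc$rb[[h]]
      dSh <- dS_sum[, , h]
      i0 <- as.integer(rb$i0)
      w0 <- as.numeric(dSh * (1 - rb$frac))
      w1 <- as.numeric(dSh * rb$frac)
      s0 <- rowsum(w0, i0)
      drel[h, as.integer(rownames(s0))] <- drel[h, as.integer(rownames(s0))] + s0[, 1]
      s1 <- rowsum(w1, i0 + 1L)
      drel[h, as.integer(rownames(s1))] <- drel[h, as.integer(rownames(s1))] + s1[, 1]
      tb <- lp$relpos[h, ]
      interior <- rb$frac > 0 & rb$frac < 1
      slope <- tb[rb$i0 + 1] - tb[rb$i0]
      d_delta <- d_delta - sum(dSh[interior] * slope[interior])
    }
    dFS <- dFS + dQ %*% t(lp$q$W)
    g_layers[[l]] <- list(q = list(W = crossprod(FS, dQ), b = colSums(dQ)),
                          k = list(W = crossprod(cc$X, dK), b = colSums(dK)),
                          v = list(W = crossprod(cc$X, dV), b = colSums(dV)),
                          relpos = drel)
    dX_next <- dK %*% t(lp$k$W) + dV %*% t(lp$v$W) + dX
  }
  list(dFS = dFS, dFM = dX_next,
       g = list(delta = d_delta, layers = g_layers))
}

#' Construct a token sequence
#'
#' A modality's encoded feature sequence at the model token rate.
#'
#' @param features `[T, d]` numeric matrix.
#' @param modality `"S"`, `"I"` or `"E"`.
#' @param token_rate Tokens per second.
#' @param validity Length-`T` logical validity flags.
#' @return A `token_sequence`.
#' @export
token_sequence <- function(features, modality = c("S", "I", "E"),
                           token_rate = 25, validity = NULL) {
  features <- as.matrix(features)
  stopif(any(!is.finite(features)), "token features must be finite")
  out <- list(features = features, modality = match.arg(modality),
              token_rate = token_rate,
              validity = validity %||% rep(TRUE, nrow(features)))
  class(out) <- "token_sequence"
  out
}

#' @export
print.token_sequence <- function(x, ...) {
  cat(sprintf("<token_sequence %s> %d tokens x %d dims @ %g Hz (%d valid)\n",
              x$modality, nrow(x$features), ncol(x$features), x$token_rate,
              sum(x$validity)))
  invisible(x)
}

#' Cross-modal temporal alignment attention
#'
#' Aligns one sensor token sequence onto the visual anchor: queries come
#' from the anchor, keys/values from the sensor stream restricted to the
#' local neighbourhood `[t - W, t + W]` (truncated and renormalized at the
#' sequence edges), with the learnable offset `state$delta` entering through
#' a continuous-lag relative position bias.
#'
#' @param anchor A `token_sequence` (modality S) or `[T, d]` matrix.
#' @param sensor A `token_sequence` (modality I or E) or `[T, d]` matrix.
#' @param cfg An [alignment_config()].
#' @param state State from [init_alignment_state()].
#' @return An `aligned_features` object: `f_hat` (`[T, d]`), `attn`
#'   (`[T, T, heads, layers]`, each row a probability distribution over the
#'   in-band keys), and the current `delta`.
#' @export
align <- function(anchor, sensor, cfg, state) {
  FA <- if (inherits(anchor, "token_sequence")) anchor$features else as.matrix(anchor)
  FM <- if (inherits(sensor, "token_sequence")) sensor$features else as.matrix(sensor)
  stopif(nrow(FA) < 1, "empty anchor sequence")
  stopif(!all(dim(FA) == dim(FM)), "anchor and sensor must share T and d")
  stopif(ncol(FA) != cfg$d_model, "feature width does not match cfg$d_model")
  kv <- if (inherits(sensor, "token_sequence")) sensor$validity else NULL
  fwd <- align_fwd(FA, FM, state, cfg, B = 1L, T = nrow(FA), key_valid = kv)
  out <- list(f_hat = fwd$Y, attn = fwd$attn[, , , 1, , drop = FALSE],
              delta = state$delta)
  dim(out$attn) <- dim(fwd$attn)[c(1, 2, 3, 5)]
  class(out) <- "aligned_features"
  out
}

#' Expected temporal lag of an attention row
#'
#' The diagnostic `E[k - t] = sum_k A_{t,k} (k - t)`: when alignment has
#' absorbed the inter-stream lag, the mean expected lag over interior query
#' positions estimates the learned offset.
#'
#' @param attn_row Probability vector over key positions `1..T`.
#' @param t Query position (1-based).
#' @return The expected lag in tokens.
#' @export
expected_lag <- function(attn_row, t) {
  stopif(abs(sum(attn_row) - 1) > 1e-4, "attention row is not normalized")
  sum(attn_row * (seq_along(attn_row) - t))
}

#' Mean expected lag of an alignment result
#'
#' Averages [expected_lag()] over heads (final layer) and interior query
#' positions, skipping boundary rows whose neighbourhood is truncated.
#'
#' @param aligned An `aligned_features` from [align()].
#' @param window_radius The alignment window radius used.
#' @return Scalar mean expected lag in tokens.
#' @export
mean_expected_lag <- function(aligned, window_radius) {
  A <- aligned$attn
  T <- dim(A)[1]
  L <- dim(A)[4]
  interior <- (window_radius + 1):(T - window_radius)
  stopif(length(interior) < 1, "sequence too short for interior rows")
  vals <- c()
  for (h in seq_len(dim(A)[3])) {
    for (t in interior) vals <- c(vals, expected_lag(A[t, , h, L], t))
  }
  mean(vals)
}

#' Fit the alignment offset on a reconstruction objective
#'
#' Trains only the temporal offset `delta` and the relative-position tables
#' (projections frozen) by Adam on the mean squared error between the
#' aligned sensor features and the value-projected anchor, the
#' reconstruction target when the sensor stream is a lagged copy of the
#' anchor.
#'
#' @param anchor,sensor `[T, d]` matrices or `token_sequence`s.
#' @param cfg An [alignment_config()].
#' @param state Initial state ([init_alignment_state()]).
#' @param steps Gradient steps.
#' @param lr Adam learning rate.
#' @return `list(state=, history=)`; `history` has per-step loss and mean
#'   expected lag.
#' @export
fit_alignment <- function(anchor, sensor, cfg, state, steps = 150, lr = 0.05) {
  FA <- if (inherits(anchor, "token_sequence")) anchor$features else as.matrix(anchor)
  FM <- if (inherits(sensor, "token_sequence")) sensor$features else as.matrix(sensor)
  T <- nrow(FA)
  opt_par <- list(delta = state$delta,
                  relpos = lapply(state$layers, `[[`, "relpos"))
  opt <- adamw_init(opt_par)
  hist <- data.frame(step = integer(0), loss = numeric(0), lag = numeric(0))
  for (s in seq_len(steps)) {
    fwd <- align_fwd(FA, FM, state, cfg, B = 1L, T = T)
    # target: value projection of the anchor through the final layer's W_v
    lpL <- state$layers[[cfg$layers]]
    target <- add_row_vec(FA %*% lpL$v$W, lpL$v$b)
    resid <- fwd$Y - target
    loss <- mean(resid^2)
    bwd <- align_bwd(2 * resid / length(resid), fwd, state, cfg, B = 1L, T = T, FS = FA)
    g <- list(delta = bwd$g$delta,
              relpos = lapply(bwd$g$layers, `[[`, "relpos"))
    st <- adamw_step(opt_par, g, opt, lr = lr, weight_decay = 0)
    opt_par <- st$params; opt <- st$state
    state$delta <- opt_par$delta
    for (l in seq_len(cfg$layers)) state$layers[[l]]$relpos <- opt_par$relpos[[l]]
    al <- list(attn = fwd$attn[, , , 1, , drop = FALSE])
    dim(al$attn) <- dim(fwd$attn)[c(1, 2, 3, 5)]
    hist <- rbind(hist, data.frame(step = s, loss = loss,
                                   lag = mean_expected_lag(al, cfg$window_radius)))
  }
  list(state = state, history = hist)
}
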