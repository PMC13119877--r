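# Minimal neural-network kernel: dense/transformer building blocks with
# hand-derived backward passes. Activations are stored batch-major: a batch
# of B windows of T steps and d channels is one (B*T) x d matrix whose rows
# (b-1)*T + t hold window b, step t. All blocks are pure functions
# (forward returns an explicit cache; backward consumes it), which keeps
# them finite-difference checkable.

add_row_vec <- function(M, v) {
  M + rep.int(v, rep.int(nrow(M), length(v)))
}

nn_init_linear <- function(n_in, n_out, scale = 1) {
  list(W = matrix(stats::rnorm(n_in * n_out), n_in, n_out) *
         (scale * sqrt(2 / (n_in + n_out))),
       b = numeric(n_out))
}

nn_linear_fwd <- function(X, p) {
  list(Y = add_row_vec(X %*% p$W, p$b), X = X)
}
nn_linear_bwd <- function(dY, cache, p) {
  list(dX = dY %*% t(p$W),
       g = list(W = crossprod(cache$X, dY), b = colSums(dY)))
}

nn_init_layernorm <- function(d) list(g = rep(1, d), b = numeric(d))

nn_layernorm_fwd <- function(X, p, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xh <- xc * inv
  list(Y = add_row_vec(xh %*% diag(p$g, ncol(X)), p$b), xh = xh, inv = inv)
}
nn_layernorm_bwd <- function(dY, cache, p) {
  dxh <- dY %*% diag(p$g, ncol(dY))
  m1 <- rowMeans(dxh)
  m2 <- rowMeans(dxh * cache$xh)
  dX <- cache$inv * (dxh - m1 - cache$xh * m2)
  list(dX = dX, g = list(g = colSums(dY * cache$xh), b = colSums(dY)))
}

# GELU, tanh approximation (the standard fast form):
# 0.5 x (1 + tanh(sqrt(2/pi) (x + 0.044715 x^3)))
nn_gelu_fwd <- function(X) {
  c0 <- 0.7978845608028654
  X2 <- X * X
  th <- tanh(c0 * (X + 0.044715 * (X2 * X)))
  list(Y = 0.5 * X * (1 + th), X = X, X2 = X2, th = th)
}
nn_gelu_bwd <- function(dY, cache) {
  c0 <- 0.7978845608028654
  X <- cache$X; th <- cache$th
  dY * (0.5 * (1 + th) +
          0.5 * X * (1 - th * th) * c0 * (1 + 3 * 0.044715 * cache$X2))
}

nn_dropout_fwd <- function(X, p, train) {
  if (!train || p <= 0) return(list(Y = X, mask = NULL))
  mask <- matrix((stats::runif(length(X)) >= p) / (1 - p), nrow(X), ncol(X))
  list(Y = X * mask, mask = mask)
}
nn_dropout_bwd <- function(dY, cache) {
  if (is.null(cache$mask)) dY else dY * cache$mask
}

softmax_rows <- function(S) {
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - m)
  E / rowSums(E)
}

# Sinusoidal absolute positions, one row per step.
positional_encoding <- function(T, d) {
  pos <- matrix(0, T, d)
  t <- seq_len(T) - 1
  for (i in seq_len(ceiling(d / 2))) {
    w <- 1 / 10000^(2 * (i - 1) / d)
    pos[, 2 * i - 1] <- sin(w * t)
    if (2 * i <= d) pos[, 2 * i] <- cos(w * t)
  }
  pos
}

nn_init_mha <- function(d) {
  list(q = nn_init_linear(d, d), k = nn_init_linear(d, d),
       v = nn_init_linear(d, d), o = nn_init_linear(d, d))
}

# Multi-head self-attention over each window independently.
# bias: optional [T, T, heads] additive logits shared across the batch.
# key_valid: optional length-(B*T) logical; invalid keys get -1e30 logits.
nn_mha_fwd <- function(X, p, heads, B, T, bias = NULL, key_valid = NULL) {
  d <- ncol(X)
  dh <- d %/% heads
  scal <- 1 / sqrt(dh)
  QKV <- add_row_vec(X %*% cbind(p$q$W, p$k$W, p$v$W), c(p$q$b, p$k$b, p$v$b))
  Q <- QKV[, 1:d, drop = FALSE]
  K <- QKV[, (d + 1):(2 * d), drop = FALSE]
  V <- QKV[, (2 * d + 1):(3 * d), drop = FALSE]
  O <- matrix(0, nrow(X), d)
  Parr <- array(0, dim = c(T, T, heads, B))
  for (b in seq_len(B)) {
    rows <- ((b - 1) * T + 1):(b * T)
    kv <- if (is.null(key_valid)) NULL else key_valid[rows]
    for (h in seq_len(heads)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      S <- (Q[rows, cols, drop = FALSE] %*% t(K[rows, cols, drop = FALSE])) * scal
      if (!is.null(bias)) S <- S + bias[, , h]
      if (!is.null(kv) && !all(kv)) S[, !kv] <- -1e30
      P <- softmax_rows(S)
      Parr[, , h, b] <- P
      O[rows, cols] <- P %*% V[rows, cols, drop = FALSE]
    }
  }
  Y <- add_row_vec(O %*% p$o$W, p$o$b)
  list(Y = Y, X = X, Q = Q, K = K, V = V, O = O, P = Parr)
}

nn_mha_bwd <- function(dY, cache, p, heads, B, T, has_bias = FALSE) {
  d <- ncol(dY)
  dh <- d %/% heads
  scal <- 1 / sqrt(dh)
  dO <- dY %*% t(p$o$W)
  g_o <- list(W = crossprod(cache$O, dY), b = colSums(dY))
  dQ <- matrix(0, nrow(dY), d); dK <- dQ; dV <- dQ
  dbias <- if (has_bias) array(0, dim = c(T, T, heads)) else NULL
  for (b in seq_len(B)) {
    rows <- ((b - 1) * T + 1):(b * T)
    for (h in seq_len(heads)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      P <- cache$P[, , h, b]
      dOb <- dO[rows, cols, drop = FALSE]
      Vb <- cache$V[rows, cols, drop = FALSE]
      dP <- dOb %*% t(Vb)
      dV[rows, cols] <- dV[rows, cols] + crossprod(P, dOb)
      dS <- P * (dP - rowSums(P * dP))
      if (has_bias) dbias[, , h] <- dbias[, , h] + dS
      dQ[rows, cols] <- (dS %*% cache$K[rows, cols, drop = FALSE]) * scal
      dK[rows, cols] <- (crossprod(dS, cache$Q[rows, cols, drop = FALSE])) * scal
    }
  }
  dX <- dQ %*% t(p$q$W) + dK %*% t(p$k$W) + dV %*% t(p$v$W)
  list(dX = dX,
       g = list(q = list(W = crossprod(cache$X, dQ), b = colSums(dQ)),
                k = list(W = crossprod(cache$X, dK), b = colSums(dK)),
                v = list(W = crossprod(cache$X, dV), b = colSums(dV)),
                o = g_o),
       dbias = dbias)
}

nn_init_tf_layer <- function(d, ffn) {
  list(ln1 = nn_init_layernorm(d), attn = nn_init_mha(d),
       ln2 = nn_init_layernorm(d),
       ffn1 = nn_init_linear(d, ffn), ffn2 = nn_init_linear(ffn, d))
}

# Pre-norm transformer layer: X + Attn(LN(X)), then U + FFN(LN(U)).
nn_tf_layer_fwd <- function(X, p, heads, B, T, bias = NULL, key_valid = NULL,
                            dropout = 0, train = FALSE) {
  ln1 <- nn_layernorm_fwd(X, p$ln1)
  at <- nn_mha_fwd(ln1$Y, p$attn, heads, B, T, bias = bias, key_valid = key_valid)
  dr1 <- nn_dropout_fwd(at$Y, dropout, train)
  U <- X + dr1$Y
  ln2 <- nn_layernorm_fwd(U, p$ln2)
  f1 <- nn_linear_fwd(ln2$Y, p$ffn1)
  ge <- nn_gelu_fwd(f1$Y)
  f2 <- nn_linear_fwd(ge$Y, p$ffn2)
  dr2 <- nn_dropout_fwd(f2$Y, dropout, train)
  list(Y = U + dr2$Y, ln1 = ln1, at = at, dr1 = dr1, U = U, ln2 = ln2,
       f1 = f1, ge = ge, f2 = f2, dr2 = dr2)
}

nn_tf_layer_bwd <- function(dY, cache, p, heads, B, T, has_bias = FALSE) {
  dU <- dY
  df2 <- nn_dropout_bwd(dY, cache$dr2)
  b2 <- nn_linear_bwd(df2, cache$f2, p$ffn2)
  dge <- nn_gelu_bwd(b2$dX, cache$ge)
  b1 <- nn_linear_bwd(dge, cache$f1, p$ffn1)
  bln2 <- nn_layernorm_bwd(b1$dX, cache$ln2, p$ln2)
  dU <- dU + bln2$dX
  dX <- dU
  dat <- nn_dropout_bwd(dU, cache$dr1)
  bat <- nn_mha_bwd(dat, cache$at, p$attn, heads, B, T, has_bias = has_bias)
  bln1 <- nn_layernorm_bwd(bat$dX, cache$ln1, p$ln1)
  dX <- dX + bln1$dX
  list(dX = dX,
       g = list(ln1 = bln1$g, attn = bat$g, ln2 = bln2$g,
                ffn1 = b1$g, ffn2 = b2$g),
       dbias = bat$dbias)
}

# Mean-pool each window from T steps to T/r tokens (r = stride factor).
nn_pool_fwd <- function(X, B, T, r) {
  stopif(T %% r != 0, "token rate must divide the grid length")
  Tt <- T %/% r
  tvec <- rep(seq_len(T), B)
  bvec <- rep(seq_len(B), each = T)
  group <- (bvec - 1L) * Tt + ceiling(tvec / r)
  Y <- rowsum(X, group) / r
  rownames(Y) <- NULL
  list(Y = Y, group = group, r = r)
}
nn_pool_bwd <- function(dY, cache) dY[cache$group, , drop = FALSE] / cache$r

# ---- AdamW -----------------------------------------------------------------

zero_like <- function(p) {
  if (is.list(p)) lapply(p, zero_like)
  else if (is.null(dim(p))) numeric(length(p))
  else array(0, dim = dim(p))
}

# Decoupled weight decay (applied to weight matrices only, not to vectors:
# biases, gains, scalar offsets, bias tables).
adamw_init <- function(params) list(m = zero_like(params), v = zero_like(params), t = 0L)

adamw_step <- function(params, grads, state, lr, weight_decay = 1e-2,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      nms <- names(p)
      for (i in seq_along(p)) {
        key <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else i
        gi <- if (is.list(g) || is.null(g)) g[[key]] else NULL
        r <- rec(p[[i]], gi, m[[i]], v[[i]])
        p[[i]] <- r$p; m[[i]] <- r$m; v[[i]] <- r$v
      }
      return(list(p = p, m = m, v = v))
    }
    if (is.null(g)) return(list(p = p, m = m, v = v))
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    wd <- if (is.matrix(p)) weight_decay else 0
    p <- p - lr * (mh / (sqrt(vh) + eps) + wd * p)
    list(p = p, m = m, v = v)
  }
  r <- rec(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

# Elementwise sum of two grad trees with identical structure.
grad_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) {
    nms <- names(a)
    for (i in seq_along(a)) {
      key <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else i
      a[[i]] <- grad_add(a[[i]], b[[key]])
    }
    return(a)
  }
  a + b
}

grad_scale <- function(a, s) {
  if (is.list(a)) return(lapply(a, grad_scale, s = s))
  a * s
}

#' Cosine-annealed learning rate
#'
#' @param epoch Zero-based epoch index.
#' @param n_epochs Total epochs.
#' @param lr_start,lr_end Schedule endpoints.
#' @return Learning rate for `epoch`; equals `lr_start` at epoch 0 and
#'   `lr_end` at the final epoch.
#' @export
cosine_lr <- function(epoch, n_epochs, lr_start = 1e-4, lr_end = 1e-6) {
  if (n_epochs <= 1) return(lr_start)
  lr_end + 0.5 * (lr_start - lr_end) * (1 + cos(pi * epoch / (n_epochs - 1)))
}

# softplus with the overflow-safe identity branch
softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
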