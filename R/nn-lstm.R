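# LSTM kernel with hand-derived backpropagation through time.
# Gate column order in the packed 4H weight matrices: input, forget, cell,
# output (i, f, g, o).

nn_init_lstm <- function(n_in, hidden) {
  p <- nn_init_linear(n_in, 4 * hidden)
  list(Wx = p$W,
       Wh = matrix(stats::rnorm(hidden * 4 * hidden), hidden, 4 * hidden) *
         sqrt(1 / hidden),
       b = c(numeric(hidden), rep(1, hidden), numeric(2 * hidden)))  # forget bias 1
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# One direction over a batch-major (B*T) x Cin input; `reverse` runs time
# backwards. Returns the (B*T) x H hidden sequence.
nn_lstm_fwd <- function(X, p, B, T, reverse = FALSE) {
  H <- ncol(p$Wh) %/% 4
  n <- nrow(X)
  G <- add_row_vec(X %*% p$Wx, p$b)
  Hout <- matrix(0, n, H)
  h <- matrix(0, B, H)
  cst <- matrix(0, B, H)
  order_t <- if (reverse) rev(seq_len(T)) else seq_len(T)
  steps <- vector("list", T)
  i1 <- 1:H; i2 <- (H + 1):(2 * H); i3 <- (2 * H + 1):(3 * H); i4 <- (3 * H + 1):(4 * H)
  for (k in seq_len(T)) {
    t <- order_t[k]
    rows <- (seq_len(B) - 1L) * T + t
    g_t <- G[rows, , drop = FALSE] + h %*% p$Wh
    gi <- sigmoid(g_t[, i1, drop = FALSE])
    gf <- sigmoid(g_t[, i2, drop = FALSE])
    gg <- tanh(g_t[, i3, drop = FALSE])
    go <- sigmoid(g_t[, i4, drop = FALSE])
    c_prev <- cst
    cst <- gf * c_prev + gi * gg
    tc <- tanh(cst)
    h_prev <- h
    h <- go * tc
    Hout[rows, ] <- h
    steps[[k]] <- list(gi = gi, gf = gf, gg = gg, go = go, c_prev = c_prev,
                       tc = tc, h_prev = h_prev, rows = rows)
  }
  list(Y = Hout, X = X, steps = steps, order_t = order_t, H = H)
}

nn_lstm_bwd <- function(dY, cache, p, B, T) {
  H <- cache$H
  n <- nrow(dY)
  dG <- matrix(0, n, 4 * H)
  dWh <- matrix(0, H, 4 * H)
  dh_next <- matrix(0, B, H)
  dc_next <- matrix(0, B, H)
  for (k in rev(seq_len(T))) {
    st <- cache$steps[[k]]
    dh <- dY[st$rows, , drop = FALSE] + dh_next
    dgo <- dh * st$tc
    dc <- dc_next + dh * st$go * (1 - st$tc^2)
    dgi <- dc * st$gg
    dgg <- dc * st$gi
    dgf <- dc * st$c_prev
    dc_next <- dc * st$gf
    dg_t <- cbind(dgi * st$gi * (1 - st$gi), dgf * st$gf * (1 - st$gf),
                  dgg * (1 - st$gg^2), dgo * st$go * (1 - st$go))
    dG[st$rows, ] <- dg_t
    dWh <- dWh + crossprod(st$h_prev, dg_t)
    dh_next <- dg_t %*% t(p$Wh)
  }
  list(dX = dG %*% t(p$Wx),
       g = list(Wx = crossprod(cache$X, dG), Wh = dWh, b = colSums(dG)))
}

nn_init_bilstm <- function(n_in, hidden, layers) {
  out <- list()
  for (l in seq_len(layers)) {
    cin <- if (l == 1) n_in else 2 * hidden
    out[[l]] <- list(fwd = nn_init_lstm(cin, hidden), bwd = nn_init_lstm(cin, hidden))
  }
  out
}

nn_bilstm_fwd <- function(X, p, B, T) {
  caches <- vector("list", length(p))
  for (l in seq_along(p)) {
    f <- nn_lstm_fwd(X, p[[l]]$fwd, B, T, reverse = FALSE)
    r <- nn_lstm_fwd(X, p[[l]]$bwd, B, T, reverse = TRUE)
    caches[[l]] <- list(f = f, r = r)
    X <- cbind(f$Y, r$Y)
  }
  list(Y = X, caches = caches)
}

nn_bilstm_bwd <- function(dY, cache, p, B, T) {
  g <- vector("list", length(p))
  for (l in rev(seq_along(p))) {
    H <- cache$caches[[l]]$f$H
    bf <- nn_lstm_bwd(dY[, 1:H, drop = FALSE], cache$caches[[l]]$f, p[[l]]$fwd, B, T)
    br <- nn_lstm_bwd(dY[, (H + 1):(2 * H), drop = FALSE], cache$caches[[l]]$r,
                      p[[l]]$bwd, B, T)
    g[[l]] <- list(fwd = bf$g, bwd = br$g)
    dY <- bf$dX + br$dX
  }
  list(dX = dY, g = g)
}
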