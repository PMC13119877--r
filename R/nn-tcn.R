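# Dilated temporal convolutions (non-causal, symmetric zero padding) for the
# EMG encoder, implemented as gather + one dense matmul per convolution.

nn_init_conv1d <- function(c_in, c_out, kernel) {
  p <- nn_init_linear(kernel * c_in, c_out)
  list(W = p$W, b = p$b, kernel = kernel)
}

# Tap gather indices for a centred kernel at dilation `dil`; index n+1 is
# the shared zero row of the padded input.
.conv_tap_idx <- function(B, T, kernel, dil) {
  n <- B * T
  tvec <- rep(seq_len(T), B)
  base <- seq_len(n)
  offs <- (seq_len(kernel) - (kernel + 1) / 2) * dil
  lapply(offs, function(o) {
    src_t <- tvec + o
    ifelse(src_t >= 1 & src_t <= T, base + o, n + 1L)
  })
}

nn_conv1d_fwd <- function(X, p, B, T, dil) {
  n <- nrow(X)
  idx <- .conv_tap_idx(B, T, p$kernel, dil)
  Xpad <- rbind(X, 0)
  Xcol <- do.call(cbind, lapply(idx, function(ix) Xpad[ix, , drop = FALSE]))
  list(Y = add_row_vec(Xcol %*% p$W, p$b), Xcol = Xcol, idx = idx, c_in = ncol(X))
}

nn_conv1d_bwd <- function(dY, cache, p) {
  dXcol <- dY %*% t(p$W)
  n <- nrow(dY)
  dXpad <- matrix(0, n + 1, cache$c_in)
  for (j in seq_along(cache$idx)) {
    blk <- dXcol[, ((j - 1) * cache$c_in + 1):(j * cache$c_in), drop = FALSE]
    ix <- cache$idx[[j]]
    keep <- ix <= n            # each valid source row written at most once per tap
    dXpad[ix[keep], ] <- dXpad[ix[keep], , drop = FALSE] + blk[keep, , drop = FALSE]
  }
  list(dX = dXpad[seq_len(n), , drop = FALSE],
       g = list(W = crossprod(cache$Xcol, dY), b = colSums(dY), kernel = NULL))
}

nn_init_tcn <- function(d, kernel, dilations) {
  lapply(dilations, function(dl)
    list(conv1 = nn_init_conv1d(d, d, kernel), conv2 = nn_init_conv1d(d, d, kernel)))
}

# Residual block: x + gelu(conv2(gelu(conv1(x)))), both convs at the block's
# dilation.
nn_tcn_fwd <- function(X, p, B, T, dilations) {
  caches <- vector("list", length(p))
  for (i in seq_along(p)) {
    c1 <- nn_conv1d_fwd(X, p[[i]]$conv1, B, T, dilations[i])
    g1 <- nn_gelu_fwd(c1$Y)
    c2 <- nn_conv1d_fwd(g1$Y, p[[i]]$conv2, B, T, dilations[i])
    g2 <- nn_gelu_fwd(c2$Y)
    caches[[i]] <- list(c1 = c1, g1 = g1, c2 = c2, g2 = g2)
    X <- X + g2$Y
  }
  list(Y = X, caches = caches)
}

nn_tcn_bwd <- function(dY, cache, p, B, T) {
  g <- vector("list", length(p))
  for (i in rev(seq_along(p))) {
    cc <- cache$caches[[i]]
    dg2 <- nn_gelu_bwd(dY, cc$g2)
    b2 <- nn_conv1d_bwd(dg2, cc$c2, p[[i]]$conv2)
    dg1 <- nn_gelu_bwd(b2$dX, cc$g1)
    b1 <- nn_conv1d_bwd(dg1, cc$c1, p[[i]]$conv1)
    g[[i]] <- list(conv1 = b1$g, conv2 = b2$g)
    dY <- dY + b1$dX
  }
  list(dX = dY, g = g)
}

#' Receptive field of a dilated convolution stack
#'
#' Closed form for a stack of residual blocks with two centred convolutions
#' of the given kernel size per block, one block per dilation:
#' `1 + 2 * (kernel - 1) * sum(dilations)` input samples.
#'
#' @param kernel Kernel size (odd).
#' @param dilations Integer vector of per-block dilation factors.
#' @return Receptive field in input samples.
#' @export
tcn_receptive_field <- function(kernel, dilations) {
  1 + 2 * (kernel - 1) * sum(dilations)
}
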