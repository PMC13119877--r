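# Interleaved multimodal backbone: interleaving bijection, bias-free
# reduction, brute-force oracle, convexity bound and the global receptive
# field.

test_that("interleaving follows the S,I,E-per-step pattern and inverts exactly", {
  set.seed(1)
  T <- 2L; d <- 4L
  fs <- matrix(rnorm(T * d), T, d)
  fi <- matrix(rnorm(T * d), T, d)
  fe <- matrix(rnorm(T * d), T, d)
  x <- interleave(fs, fi, fe)
  expect_equal(x$modality_ids, c(1L, 2L, 3L, 1L, 2L, 3L))
  expect_equal(x$time_ids, c(0L, 0L, 0L, 1L, 1L, 1L))
  back <- deinterleave_aggregate(x)
  expect_identical(back$H_S, fs)
  expect_identical(back$H_I, fi)
  expect_identical(back$H_E, fe)
  # 100-step windows produce a 300-token joint sequence
  T2 <- 100L
  x2 <- interleave(matrix(0, T2, 2), matrix(0, T2, 2), matrix(0, T2, 2))
  expect_equal(nrow(x2$tokens), 300L)
  expect_error(interleave(fs, fi[1, , drop = FALSE], fe), "share T and d")
  bad <- x; bad$modality_ids <- rev(bad$modality_ids)
  expect_error(deinterleave_aggregate(bad), "malformed")
})

test_that("modality-constant tokens de-interleave into constant streams", {
  T <- 5L
  x <- interleave(matrix(1, T, 3), matrix(2, T, 3), matrix(3, T, 3))
  out <- deinterleave_aggregate(x)
  expect_true(all(out$H_S == 1) && all(out$H_I == 2) && all(out$H_E == 3))
})

# Independent scalar-loop implementation of one pre-norm layer with biased
# attention (no shared code with the package internals).
brute_layer <- function(X, p, bias, heads) {
  n <- nrow(X); d <- ncol(X); dh <- d / heads
  ln <- function(x, g, b) {
    mu <- mean(x); v <- mean((x - mu)^2)
    (x - mu) / sqrt(v + 1e-5) * g + b
  }
  H1 <- t(apply(X, 1, ln, g = p$ln1$g, b = p$ln1$b))
  Q <- H1 %*% p$attn$q$W + matrix(p$attn$q$b, n, d, byrow = TRUE)
  K <- H1 %*% p$attn$k$W + matrix(p$attn$k$b, n, d, byrow = TRUE)
  V <- H1 %*% p$attn$v$W + matrix(p$attn$v$b, n, d, byrow = TRUE)
  O <- matrix(0, n, d)
  for (h in seq_len(heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    for (i in seq_len(n)) {
      logit <- numeric(n)
      for (j in seq_len(n)) {
        logit[j] <- sum(Q[i, cols] * K[j, cols]) / sqrt(dh) + bias[i, j, h]
      }
      w <- exp(logit - max(logit)); w <- w / sum(w)
      for (j in seq_len(n)) O[i, cols] <- O[i, cols] + w[j] * V[j, cols]
    }
  }
  U <- X + O %*% p$attn$o$W + matrix(p$attn$o$b, n, d, byrow = TRUE)
  H2 <- t(apply(U, 1, ln, g = p$ln2$g, b = p$ln2$b))
  A1 <- H2 %*% p$ffn1$W + matrix(p$ffn1$b, n, ncol(p$ffn1$W), byrow = TRUE)
  G <- 0.5 * A1 * (1 + tanh(sqrt(2 / pi) * (A1 + 0.044715 * A1^3)))
  U + G %*% p$ffn2$W + matrix(p$ffn2$b, n, d, byrow = TRUE)
}

test_that("backbone layer matches a brute-force scalar implementation", {
  cfg <- backbone_config(layers = 1L, heads = 1L, d_model = 6L, ffn = 9L,
                         dropout = 0, max_lag = 3L)
  for (seed in 1:5) {
    bk <- with_seed(seed, init_backbone(cfg, T_tokens = 3L))
    X <- with_seed(seed + 50, matrix(rnorm(9 * 6), 9, 6))   # 3 steps x 3 modalities
    seqx <- interleave(X[seq(1, 9, 3), ], X[seq(2, 9, 3), ], X[seq(3, 9, 3), ])
    out <- encoder_layer(seqx, bk$layers[[1]], cfg, bk$layers[[1]]$tf)
    idx <- motionfuse:::.backbone_bias_idx(3L, 3L)
    bias <- motionfuse:::.backbone_bias(bk$layers[[1]], idx, 1L)
    oracle <- brute_layer(seqx$tokens, bk$layers[[1]]$tf, bias, heads = 1L)
    expect_lt(max(abs(out$tokens - oracle)), 1e-5)
  }
})

test_that("attention rows are stochastic and outputs obey the convexity bound", {
  cfg <- backbone_config(layers = 1L, heads = 2L, d_model = 8L, ffn = 12L,
                         dropout = 0, max_lag = 4L)
  for (seed in 1:20) {
    bk <- with_seed(seed, init_backbone(cfg, 4L))
    T <- 4L
    fs <- with_seed(seed + 1, matrix(rnorm(T * 8), T, 8))
    fi <- with_seed(seed + 2, matrix(rnorm(T * 8), T, 8))
    fe <- with_seed(seed + 3, matrix(rnorm(T * 8), T, 8))
    x <- interleave(fs, fi, fe)
    out <- encoder_layer(x, bk$layers[[1]], cfg, bk$layers[[1]]$tf)
    P <- attr(out, "attn")
    expect_lt(max(abs(apply(P, c(1, 3), sum) - 1)), 1e-6)
    # pre-projection attention output: convex combination of value rows
    ln1 <- motionfuse:::nn_layernorm_fwd(x$tokens, bk$layers[[1]]$tf$ln1)
    V <- motionfuse:::add_row_vec(ln1$Y %*% bk$layers[[1]]$tf$attn$v$W,
                                  bk$layers[[1]]$tf$attn$v$b)
    for (h in 1:2) {
      cols <- ((h - 1) * 4 + 1):(h * 4)
      agg <- P[, , h] %*% V[, cols]
      expect_lte(max(sqrt(rowSums(agg^2))),
                 max(sqrt(rowSums(V[, cols]^2))) + 1e-6)
    }
  }
})

test_that("zero bias tables reduce the layer to a plain pre-norm transformer", {
  cfg <- backbone_config(layers = 1L, heads = 2L, d_model = 8L, ffn = 12L,
                         dropout = 0, max_lag = 4L)
  bk <- with_seed(2, init_backbone(cfg, 4L))
  bk$layers[[1]]$b_time[] <- 0
  bk$layers[[1]]$b_modal[] <- 0
  x <- interleave(with_seed(3, matrix(rnorm(32), 4, 8)),
                  with_seed(4, matrix(rnorm(32), 4, 8)),
                  with_seed(5, matrix(rnorm(32), 4, 8)))
  out <- encoder_layer(x, bk$layers[[1]], cfg, bk$layers[[1]]$tf)
  plain <- nn_tf_layer_fwd(x$tokens, bk$layers[[1]]$tf, 2L, 1L, 12L)
  expect_lt(max(abs(out$tokens - plain$Y)), 1e-6)
})

test_that("one layer already provides a global receptive field", {
  cfg <- backbone_config(layers = 1L, heads = 1L, d_model = 4L, ffn = 6L,
                         dropout = 0, max_lag = 3L)
  bk <- with_seed(6, init_backbone(cfg, 3L))
  x0 <- with_seed(7, matrix(rnorm(9 * 4), 9, 4))
  f0 <- backbone_fwd(x0, bk, cfg, 1L, 3L)$Y
  # perturb the last input token; every output token must respond
  x1 <- x0
  x1[9, 1] <- x1[9, 1] + 1e-4
  f1 <- backbone_fwd(x1, bk, cfg, 1L, 3L)$Y
  response <- rowSums(abs(f1 - f0))
  expect_true(all(response > 0))
})

test_that("invalid tokens are masked out as attention keys", {
  cfg <- backbone_config(layers = 1L, heads = 1L, d_model = 4L, ffn = 6L,
                         dropout = 0, max_lag = 3L)
  bk <- with_seed(8, init_backbone(cfg, 3L))
  fs <- with_seed(9, matrix(rnorm(12), 3, 4))
  fi <- with_seed(10, matrix(rnorm(12), 3, 4))
  fe <- with_seed(11, matrix(rnorm(12), 3, 4))
  x <- interleave(token_sequence(fs, "S"),
                  token_sequence(fi, "I", validity = c(FALSE, FALSE, FALSE)),
                  token_sequence(fe, "E"))
  out <- encoder_layer(x, bk$layers[[1]], cfg, bk$layers[[1]]$tf)
  P <- attr(out, "attn")
  imu_cols <- seq(2, 9, by = 3)
  expect_lt(max(P[, imu_cols, 1]), 1e-12)
})
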