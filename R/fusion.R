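# Uncertainty-aware fusion: per-timestep, per-modality scalar uncertainty
# (softplus of a learned score), normalized inverse-confidence weights, and
# convex aggregation, with a temporal smoothness regularizer on the fused
# stream.

#' Initialize an uncertainty head
#'
#' Two time-distributed perceptron layers with nonlinear activation mapping
#' a d-dimensional token to a scalar uncertainty score:
#' `u_t = W2 phi(W1 h_t)` (bottleneck-then-scalar reading; `phi = tanh`).
#'
#' @param d Input feature width.
#' @param hidden Bottleneck width.
#' @return Head parameter list.
#' @export
init_uncertainty_head <- function(d, hidden = 32L) {
  l1 <- nn_init_linear(d, hidden)
  l2 <- nn_init_linear(hidden, 1L)
  # near-zero output layer: fusion starts at the uniform average and only
  # departs from it as the heads learn a real reliability signal
  list(W1 = l1$W, b1 = l1$b, w2 = 0.1 * as.numeric(l2$W), b2 = 0)
}

#' Estimate per-timestep uncertainty for one modality
#'
#' @param h_m `[T, d]` feature matrix.
#' @param head Parameters from [init_uncertainty_head()].
#' @return `list(u=, sigma=)`: raw scores and their softplus
#'   `sigma = log(1 + exp(u))`, computed overflow-safely.
#' @export
estimate_uncertainty <- function(h_m, head) {
  h_m <- as.matrix(h_m)
  stopif(any(!is.finite(h_m)), "h_m must be finite")
  a <- tanh(add_row_vec(h_m %*% head$W1, head$b1))
  u <- as.numeric(a %*% head$w2) + head$b2
  stopif(!is.null(dim(u)) && length(dim(u)) > 1, "head output must be scalar per step")
  list(u = u, sigma = softplus(u))
}

#' Fusion weights from uncertainties
#'
#' Normalized inverse confidence: `omega_t = softmax(-sigma_t)` across
#' modalities, per time step. Infinite sigma (an entirely invalid modality)
#' receives weight zero with the remaining modalities renormalized.
#'
#' @param sigma `[T, 3]` matrix of non-negative uncertainties.
#' @return `[T, 3]` matrix of simplex weight rows.
#' @export
fusion_weights <- function(sigma) {
  sigma <- as.matrix(sigma)
  stopif(any(sigma < 0, na.rm = TRUE), "sigma must be >= 0")
  neg <- -sigma
  m <- apply(neg, 1, max)
  stopif(any(!is.finite(m)), "at least one modality must have finite uncertainty")
  E <- exp(neg - m)
  E[is.nan(E)] <- 0
  E / rowSums(E)
}

#' Convex fusion of modality streams
#'
#' `z_t = sum_m omega_t^(m) h_t^(m)`; every fused vector is a convex
#' combination, so `||z_t|| <= max_m ||h_t^(m)||`.
#'
#' @param h_s,h_i,h_e `[T, d]` per-modality features.
#' @param omega `[T, 3]` simplex weight rows (checked to 1e-4).
#' @return Fused `[T, d]` matrix.
#' @export
fuse <- function(h_s, h_i, h_e, omega) {
  omega <- as.matrix(omega)
  stopif(any(abs(rowSums(omega) - 1) > 1e-4) || any(omega < -1e-12),
         "omega rows must lie on the probability simplex")
  omega[, 1] * as.matrix(h_s) + omega[, 2] * as.matrix(h_i) +
    omega[, 3] * as.matrix(h_e)
}

#' Temporal smoothness penalty
#'
#' `L_smooth = sum_{t=2}^T || z_t - z_{t-1} ||^2` (squared Euclidean norm of
#' successive differences of the fused representation).
#'
#' @param z `[T, d]` fused sequence.
#' @return Scalar penalty (0 with a warning when `T < 2`).
#' @export
smoothness_penalty <- function(z) {
  z <- as.matrix(z)
  if (nrow(z) < 2) {
    warning("smoothness penalty undefined for T < 2; returning 0")
    return(0)
  }
  sum(diff(z)^2)
}

#' Analytic minimizer of the expected fusion error
#'
#' Minimizes `sum_m omega_m^2 sigma_m` over the probability simplex: the
#' optimum is `omega_m` proportional to `1 / sigma_m` (inverse-variance
#' weighting), with the objective value `(sum_m 1/sigma_m)^(-1)`. Used as a
#' test-side oracle to quantify the gap between the softmax weighting of the
#' forward path and the analytic optimum.
#'
#' @param sigma_row Triple of non-negative uncertainties.
#' @return Simplex triple of optimal weights; any zero uncertainty receives
#'   all weight (split uniformly among zeros).
#' @export
optimal_weights_oracle <- function(sigma_row) {
  stopif(length(sigma_row) != 3 || any(sigma_row < 0), "need 3 non-negative sigmas")
  if (any(sigma_row == 0)) {
    w <- as.numeric(sigma_row == 0)
    return(w / sum(w))
  }
  w <- 1 / sigma_row
  w / sum(w)
}

# ---- batched internals for the model ---------------------------------------

# valid: list of 3 logical vectors (token validity per modality); invalid
# modalities get sigma = +Inf, hence omega = 0.
fusion_fwd <- function(hs, hi, he, heads, valid = NULL) {
  n <- nrow(hs)
  hmats <- list(hs, hi, he)
  u <- matrix(0, n, 3); act <- vector("list", 3)
  for (m in 1:3) {
    a <- tanh(add_row_vec(hmats[[m]] %*% heads[[m]]$W1, heads[[m]]$b1))
    act[[m]] <- a
    u[, m] <- as.numeric(a %*% heads[[m]]$w2) + heads[[m]]$b2
  }
  sigma <- softplus(u)
  if (!is.null(valid)) for (m in 1:3) sigma[!valid[[m]], m] <- Inf
  omega <- fusion_weights(sigma)
  z <- omega[, 1] * hs + omega[, 2] * hi + omega[, 3] * he
  list(z = z, u = u, sigma = sigma, omega = omega, act = act, hmats = hmats,
       valid = valid)
}

# `du_extra` carries the uncertainty-calibration gradient; it updates the
# head parameters only (stop-gradient into the feature trunk), so the
# calibration term shapes the uncertainty readout without perturbing the
# task representation.
fusion_bwd <- function(dz, cache, heads, du_extra = NULL) {
  omega <- cache$omega
  dh <- lapply(1:3, function(m) omega[, m] * dz)
  domega <- sapply(1:3, function(m) rowSums(dz * cache$hmats[[m]]))
  # softmax over -sigma: dlogit = omega * (domega - sum(omega * domega))
  srow <- rowSums(omega * domega)
  dlogit <- omega * (domega - srow)
  dsigma <- -dlogit
  du <- dsigma * stats::plogis(cache$u)     # d softplus = sigmoid
  du_full <- if (is.null(du_extra)) du else du + du_extra
  if (!is.null(cache$valid)) {
    for (m in 1:3) {
      du[!cache$valid[[m]], m] <- 0
      du_full[!cache$valid[[m]], m] <- 0
    }
  }
  g_heads <- vector("list", 3)
  for (m in 1:3) {
    a <- cache$act[[m]]
    dum_full <- du_full[, m]
    dw2 <- as.numeric(crossprod(a, dum_full))
    dpre_full <- outer(dum_full, heads[[m]]$w2) * (1 - a^2)
    g_heads[[m]] <- list(W1 = crossprod(cache$hmats[[m]], dpre_full),
                         b1 = colSums(dpre_full), w2 = dw2,
                         b2 = sum(dum_full))
    # trunk gradient uses the task path only
    dpre_task <- outer(du[, m], heads[[m]]$w2) * (1 - a^2)
    dh[[m]] <- dh[[m]] + dpre_task %*% t(heads[[m]]$W1)
  }
  names(g_heads) <- names(heads)
  list(dhs = dh[[1]], dhi = dh[[2]], dhe = dh[[3]], g = g_heads)
}

# Smoothness penalty over a batch of windows (batch-major rows), averaged
# over windows.
smoothness_fwd <- function(z, B, T) {
  total <- 0
  for (b in seq_len(B)) {
    rows <- ((b - 1) * T + 1):(b * T)
    total <- total + sum(diff(z[rows, , drop = FALSE])^2)
  }
  total / B
}

smoothness_bwd <- function(z, B, T) {
  dz <- matrix(0, nrow(z), ncol(z))
  for (b in seq_len(B)) {
    rows <- ((b - 1) * T + 1):(b * T)
    zb <- z[rows, , drop = FALSE]
    d <- diff(zb)
    dzb <- matrix(0, T, ncol(z))
    dzb[2:T, ] <- 2 * d
    dzb[1:(T - 1), ] <- dzb[1:(T - 1), ] - 2 * d
    dz[rows, ] <- dzb / B
  }
  dz
}
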