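# Uncertainty-aware fusion: softplus mapping, inverse-confidence weights,
# convex aggregation, smoothness penalty and the inverse-variance oracle.

test_that("uncertainty head emits scalar softplus uncertainties", {
  head <- with_seed(1, init_uncertainty_head(8L, 4L))
  h <- with_seed(2, matrix(rnorm(40), 5, 8))
  out <- estimate_uncertainty(h, head)
  expect_length(out$u, 5)
  expect_true(all(out$sigma >= 0))
  expect_equal(out$sigma, softplus(out$u))
  # softplus anchor points
  expect_equal(softplus(0), log(2), tolerance = 1e-12)
  expect_lt(softplus(-50), 1e-20)
  expect_equal(softplus(50), 50, tolerance = 1e-9)
})

test_that("fusion weights are normalized inverse confidence", {
  expect_equal(fusion_weights(matrix(c(2, 2, 2), 1)), matrix(1 / 3, 1, 3),
               tolerance = 1e-12)
  w <- fusion_weights(matrix(c(0.5, 1.0, 1.5), 1))
  expect_equal(as.numeric(w), c(0.5065, 0.3072, 0.1863), tolerance = 5e-4)
  # direct evaluation of the defining formula
  expect_equal(as.numeric(w), exp(-c(0.5, 1, 1.5)) / sum(exp(-c(0.5, 1, 1.5))),
               tolerance = 1e-12)
  # sigma -> Inf sends the weight to zero with the rest renormalizing
  w2 <- fusion_weights(matrix(c(Inf, 1, 1), 1))
  expect_equal(as.numeric(w2), c(0, 0.5, 0.5))
  expect_error(fusion_weights(matrix(c(Inf, Inf, Inf), 1)), "finite")
})

test_that("fusion is an exact convex combination", {
  set.seed(3)
  hs <- matrix(rnorm(6), 3, 2); hi <- matrix(rnorm(6), 3, 2)
  he <- matrix(rnorm(6), 3, 2)
  expect_equal(fuse(hs, hi, he, matrix(c(1, 0, 0), 3, 3, byrow = TRUE)), hs)
  expect_equal(fuse(hs, hs, hs, matrix(c(0.2, 0.5, 0.3), 3, 3, byrow = TRUE)),
               hs, tolerance = 1e-12)
  om <- t(apply(matrix(runif(9), 3, 3), 1, function(x) x / sum(x)))
  z <- fuse(hs, hi, he, om)
  zo <- matrix(0, 3, 2)
  for (t in 1:3) for (j in 1:2) {
    zo[t, j] <- om[t, 1] * hs[t, j] + om[t, 2] * hi[t, j] + om[t, 3] * he[t, j]
  }
  expect_equal(z, zo, tolerance = 1e-12)
  for (t in 1:3) {
    expect_lte(sqrt(sum(z[t, ]^2)),
               max(sqrt(sum(hs[t, ]^2)), sqrt(sum(hi[t, ]^2)),
                   sqrt(sum(he[t, ]^2))) + 1e-12)
  }
  expect_error(fuse(hs, hi, he, matrix(c(0.5, 0.2, 0.2), 3, 3, byrow = TRUE)),
               "simplex")
})

test_that("smoothness penalty follows its closed form", {
  expect_equal(smoothness_penalty(matrix(5, 7, 3)), 0)
  z <- rbind(c(0, 0), c(1, 0), c(1, 1))
  expect_equal(smoothness_penalty(z), 2)
  set.seed(4)
  z2 <- matrix(rnorm(20), 10, 2)
  expect_equal(smoothness_penalty(3 * z2), 9 * smoothness_penalty(z2),
               tolerance = 1e-12)
  expect_warning(s0 <- smoothness_penalty(matrix(1, 1, 2)), "T < 2")
  expect_equal(s0, 0)
})

test_that("the inverse-variance oracle minimizes the weighted objective", {
  expect_equal(optimal_weights_oracle(c(1, 1, 1)), rep(1 / 3, 3))
  expect_equal(optimal_weights_oracle(c(1, 2, 4)), c(4, 2, 1) / 7)
  expect_equal(optimal_weights_oracle(c(0, 2, 4)), c(1, 0, 0))
  obj <- function(w, s) sum(w^2 * s)
  # grid search over the simplex at step 1e-3 confirms the closed form
  gr <- seq(0, 1, by = 1e-3)
  s <- c(1, 2, 4)
  best <- Inf; warg <- NULL
  for (w1 in gr) {
    w2 <- gr[gr <= 1 - w1 + 1e-12]
    o <- w1^2 * s[1] + w2^2 * s[2] + (1 - w1 - w2)^2 * s[3]
    i <- which.min(o)
    if (o[i] < best) { best <- o[i]; warg <- c(w1, w2[i], 1 - w1 - w2[i]) }
  }
  expect_equal(warg, c(4, 2, 1) / 7, tolerance = 2e-3)
  expect_equal(best, obj(c(4, 2, 1) / 7, s), tolerance = 1e-5)
  # 1000 random draws: oracle never loses to the softmax weighting, and the
  # optimum matches the closed form (sum 1/sigma)^(-1)
  set.seed(5)
  for (i in 1:1000) {
    s <- runif(3, 0.05, 5)
    wo <- optimal_weights_oracle(s)
    ws <- as.numeric(fusion_weights(matrix(s, 1)))
    expect_lte(obj(wo, s), obj(ws, s) + 1e-12)
    expect_equal(obj(wo, s), 1 / sum(1 / s), tolerance = 1e-9)
  }
})

test_that("forward passes conserve the simplex for every time step", {
  heads <- with_seed(6, list(s = init_uncertainty_head(8L, 4L),
                             i = init_uncertainty_head(8L, 4L),
                             e = init_uncertainty_head(8L, 4L)))
  for (seed in 1:10) {
    hs <- with_seed(seed, matrix(rnorm(80, sd = 2), 10, 8))
    hi <- with_seed(seed + 20, matrix(rnorm(80, sd = 2), 10, 8))
    he <- with_seed(seed + 40, matrix(rnorm(80, sd = 2), 10, 8))
    f <- fusion_fwd(hs, hi, he, heads)
    expect_lt(max(abs(rowSums(f$omega) - 1)), 1e-6)
    expect_true(all(f$omega >= 0))
    expect_true(all(is.finite(f$z)))
  }
  # an entirely invalid modality receives zero weight everywhere
  f2 <- fusion_fwd(matrix(0, 4, 8), matrix(0, 4, 8), matrix(0, 4, 8), heads,
                   valid = list(rep(TRUE, 4), rep(FALSE, 4), rep(TRUE, 4)))
  expect_true(all(f2$omega[, 2] == 0))
  expect_lt(max(abs(rowSums(f2$omega) - 1)), 1e-12)
})

test_that("fusion gradients match finite differences", {
  heads <- with_seed(7, list(s = init_uncertainty_head(4L, 3L),
                             i = init_uncertainty_head(4L, 3L),
                             e = init_uncertainty_head(4L, 3L)))
  hs <- with_seed(8, matrix(rnorm(12), 3, 4))
  hi <- with_seed(9, matrix(rnorm(12), 3, 4))
  he <- with_seed(10, matrix(rnorm(12), 3, 4))
  dz <- with_seed(11, matrix(rnorm(12), 3, 4))
  f <- fusion_fwd(hs, hi, he, heads)
  b <- fusion_bwd(dz, f, heads)
  expect_lt(max(abs(b$dhs - numgrad(function(x)
    sum(fusion_fwd(matrix(x, 3, 4), hi, he, heads)$z * dz), hs))), 1e-7)
  expect_lt(max(abs(b$g$i$W1 - numgrad(function(w) {
    hh <- heads; hh$i$W1 <- matrix(w, 4, 3)
    sum(fusion_fwd(hs, hi, he, hh)$z * dz)
  }, heads$i$W1))), 1e-7)
  expect_lt(abs(b$g$e$b2 - numgrad(function(v) {
    hh <- heads; hh$e$b2 <- v
    sum(fusion_fwd(hs, hi, he, hh)$z * dz)
  }, heads$e$b2)), 1e-7)
})
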