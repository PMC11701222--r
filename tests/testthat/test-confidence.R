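test_that("cosine similarity matches hand values and rejects zero vectors", {
  expect_equal(cosine_sim(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_sim(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_sim(c(1, 0), c(1, 1)), 1 / sqrt(2))
  expect_error(cosine_sim(c(0, 0), c(1, 1)), "zero")
})

test_that("confidence is the mean similarity, uncertainty its variance", {
  # prompt features chosen so the similarities to f_a are 0.6, 0.8, 1.0
  f_a <- c(1, 0)
  angle <- function(s) c(s, sqrt(1 - s^2))
  F_i <- rbind(angle(0.6), angle(0.8), angle(1.0))
  expect_equal(prompt_confidence(f_a, F_i), 0.8)
  expect_equal(prompt_uncertainty(f_a, F_i), (0.04 + 0 + 0.04) / 3)
  # self-similarity and orthogonality endpoints
  expect_equal(prompt_confidence(c(2, 1), rbind(c(2, 1))), 1)
  expect_equal(prompt_uncertainty(c(2, 1), rbind(c(2, 1))), 0)
  expect_equal(prompt_confidence(c(1, 0), rbind(c(0, 1), c(0, -2))), 0)
  expect_error(prompt_confidence(c(1, 0), matrix(0, 0, 2)), "empty")
})

test_that("confidence and uncertainty are invariant to prompt order and scale", {
  set.seed(77)
  for (rep in 1:10) {
    D <- sample(2:6, 1); n <- sample(1:8, 1)
    f_a <- rnorm(D)
    F_i <- matrix(rnorm(n * D), n, D)
    perm <- sample(n)
    scaled <- F_i * runif(n, 0.1, 10)
    expect_equal(prompt_confidence(f_a, F_i), prompt_confidence(f_a, F_i[perm, , drop = FALSE]))
    expect_equal(prompt_confidence(f_a, F_i), prompt_confidence(2.5 * f_a, scaled))
    expect_equal(prompt_uncertainty(f_a, F_i), prompt_uncertainty(3 * f_a, scaled))
  }
})

test_that("uncertainty equals a brute-force two-pass variance", {
  set.seed(13)
  for (rep in 1:25) {
    n <- sample(1:32, 1)
    f_a <- rnorm(4)
    F_i <- matrix(rnorm(n * 4), n, 4)
    s <- apply(F_i, 1, function(w) cosine_sim(f_a, w))
    m <- sum(s) / n
    expect_equal(prompt_uncertainty(f_a, F_i), sum((s - m)^2) / n)
  }
})

test_that("thresholding and the gate follow the stated indicators", {
  t <- thresholds(tau_h = 0.8, tau_l = 0.5, kappa_h = 0.2)
  expect_equal(threshold_label(c(0.85, 0.3, 0.65, 0.8, 0.5), t),
               c(1L, -1L, 0L, 1L, -1L))
  expect_equal(selection_gate(0.9, 0.1, t), 1L)
  expect_equal(selection_gate(0.9, 0.25, t), 0L)
  expect_equal(selection_gate(0.5, 0.0, t), 0L)
  # a gated pixel is necessarily foreground under the shared tau_h
  set.seed(3)
  p <- runif(200, -1, 1); u <- runif(200, 0, 0.5)
  g <- selection_gate(p, u, t)
  expect_true(all(threshold_label(p[g == 1L], t) == 1L))
  expect_error(thresholds(tau_h = 0.4, tau_l = 0.5), "tau_l < tau_h")
})

test_that("consistency loss matches hand computation and its bounds", {
  # one gated pixel, K = 2, p_own = 0.8, p_other = 0.1
  p <- matrix(c(0.8, 0.1), 1, 2)
  expect_equal(consistency_loss(p, gate = 1L, i = 1L), -(log(0.8) + log(0.9)))
  # ungated pixels contribute nothing
  expect_equal(consistency_loss(p, gate = 0L, i = 1L), 0)
  # perfect separation approaches the zero infimum
  expect_lt(consistency_loss(matrix(c(1, 0), 1, 2), 1L, 1L), 1e-5)
  expect_error(consistency_loss(matrix(0.5, 1, 1), 1L, 1L), "K >= 2")
  # non-negative after clipping, even for negative cosine means
  expect_gte(consistency_loss(matrix(c(-0.4, 0.9), 1, 2), 1L, 1L), 0)
  # monotone decreasing in the own-category confidence
  vals <- sapply(seq(0.05, 0.95, by = 0.05), function(pi)
    consistency_loss(matrix(c(pi, 0.2, 0.3), 1, 3), 1L, 1L))
  expect_true(all(diff(vals) < 0))
})

test_that("analytic projection gradient matches numerical differentiation", {
  set.seed(21)
  D <- 4
  A <- diag(D) + matrix(rnorm(D * D, sd = 0.2), D, D)
  X <- matrix(rnorm(5 * D), 5, D)
  pf <- list(matrix(rnorm(3 * D), 3, D), matrix(rnorm(2 * D), 2, D))
  gate <- c(1L, 0L, 1L, 1L, 1L)
  cat_i <- c(1L, 1L, 2L, 2L, 1L)
  lg <- ipghsi:::consistency_loss_grad(A, X, pf, gate, cat_i)
  h <- 1e-6
  num <- matrix(0, D, D)
  for (r in 1:D) for (c in 1:D) {
    Ap <- A; Ap[r, c] <- Ap[r, c] + h
    Am <- A; Am[r, c] <- Am[r, c] - h
    num[r, c] <- (ipghsi:::consistency_loss_grad(Ap, X, pf, gate, cat_i)$loss -
                  ipghsi:::consistency_loss_grad(Am, X, pf, gate, cat_i)$loss) / (2 * h)
  }
  expect_equal(lg$grad, num, tolerance = 1e-5)
  # the loss value agrees with the standalone loss on the same confidences
  P <- sapply(pf, function(W) {
    Wp <- W %*% t(A); Xp <- X %*% t(A)
    rowMeans((Xp / sqrt(rowSums(Xp^2))) %*% t(Wp / sqrt(rowSums(Wp^2))))
  })
  manual <- sum(sapply(which(gate == 1L), function(a)
    consistency_loss(P[a, , drop = FALSE], 1L, cat_i[a])))
  expect_equal(lg$loss, manual)
})
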