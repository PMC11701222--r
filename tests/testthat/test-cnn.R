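test_that("patch extraction mirrors borders and copies interiors", {
  H <- 9L; W <- 9L; C <- 3L
  cube <- hsi_cube(array(seq_len(H * W * C), c(H, W, C)))
  pd <- extract_patches(cube, data.frame(row = c(1L, 5L), col = c(1L, 5L),
                                         category = c(1L, 2L)), size = 9L)
  expect_equal(dim(pd$patches), c(2L, 81L, 3L))
  # interior pixel (5,5): the patch is the raw window
  win <- unclass(cube)[1:9, 1:9, ]
  expect_equal(array(pd$patches[2, , ], c(9, 9, 3)), win)
  # corner pixel (1,1): mirror padding reflects rows/cols 4..1 outward
  corner <- array(pd$patches[1, , ], c(9, 9, 3))
  expect_equal(corner[5:9, 5:9, ], unclass(cube)[1:5, 1:5, ])
  expect_equal(corner[4, 5, 1], cube[1, 1, 1])     # one step above centre edge
  expect_equal(corner[1, 5, 1], cube[4, 1, 1])     # mirrored row 4
  expect_error(extract_patches(cube, data.frame(row = 1, col = 1), size = 8L), "odd")
})

test_that("training sets union seeds and pseudo-labels, seeds winning conflicts", {
  seeds <- data.frame(row = 1:4, col = 1:4, category = c(1L, 1L, 2L, 2L))
  expect_equal(nrow(build_training_set(seeds)), 4L)
  pseudo <- data.frame(row = 5:7, col = 5:7, category = c(1L, 2L, 1L))
  ts <- build_training_set(seeds, pseudo)
  expect_equal(nrow(ts), 7L)
  expect_equal(sum(ts$source == "pseudo"), 3L)
  clash <- data.frame(row = c(1L, 9L), col = c(1L, 9L), category = c(2L, 1L))
  expect_message(ts2 <- build_training_set(seeds, clash), "conflict")
  expect_equal(nrow(ts2), 5L)
  expect_equal(ts2$category[ts2$row == 1L & ts2$col == 1L], 1L)  # seed kept
})

test_that("backpropagation matches numerical gradients", {
  set.seed(8)
  size <- 5L; n <- 3L; Cin <- 2L; K <- 2L
  geom <- ipghsi:::cnn_geometry(size)
  X <- array(rnorm(n * size * size * Cin), c(n, size * size, Cin))
  y <- c(1L, 2L, 1L)
  par <- list(W1 = matrix(rnorm(9 * Cin * 4, sd = 0.3), 9 * Cin, 4), b1 = rnorm(4),
              W2 = matrix(rnorm(9 * 4 * 3, sd = 0.3), 9 * 4, 3), b2 = rnorm(3),
              W3 = matrix(rnorm(3 * K, sd = 0.3), 3, K), b3 = rnorm(K))
  lossf <- function(pp) {
    lg <- ipghsi:::cnn_forward(pp, X, geom)$logits
    mx <- apply(lg, 1, max)
    sum(log(rowSums(exp(lg - mx))) + mx - lg[cbind(1:n, y)]) / n
  }
  fwd <- ipghsi:::cnn_forward(par, X, geom, want_cache = TRUE)
  mx <- apply(fwd$logits, 1, max)
  prob <- exp(fwd$logits - mx) / rowSums(exp(fwd$logits - mx))
  onehot <- matrix(0, n, K); onehot[cbind(1:n, y)] <- 1
  grads <- ipghsi:::cnn_backward(par, geom, fwd$cache, (prob - onehot) / n)
  h <- 1e-6
  for (nm in names(par)) {
    # spot-check a handful of coordinates per parameter block
    idx <- seq(1L, length(par[[nm]]), length.out = min(6, length(par[[nm]])))
    for (i in unique(round(idx))) {
      pp <- par; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- par; pm[[nm]][i] <- pm[[nm]][i] - h
      expect_equal(grads[[nm]][i], (lossf(pp) - lossf(pm)) / (2 * h),
                   tolerance = 1e-5)
    }
  }
})

test_that("training is deterministic, inert at lr 0, and fits separable data", {
  sc <- tiny_scene(seed = 6, noise_sd = 0.02, H = 20, W = 20, C = 6, K = 2)
  seeds <- sample_seed_labels(sc$truth, per_class = 8, seed = 6)
  pd <- extract_patches(sc$cube, seeds, 9L)
  m1 <- hsi_cnn(pd, train_config(epochs = 5, batch_size = 8, seed = 3))
  m2 <- hsi_cnn(pd, train_config(epochs = 5, batch_size = 8, seed = 3))
  expect_equal(m1$loss, m2$loss)
  expect_equal(m1$par, m2$par)
  # zero learning rate leaves the initialisation untouched
  f1 <- hsi_cnn(pd, train_config(epochs = 1, lr = 0, seed = 5))
  f5 <- hsi_cnn(pd, train_config(epochs = 5, lr = 0, seed = 5))
  expect_equal(f1$par, f5$par)
  # a separable two-class scene trains to perfect training accuracy
  m <- hsi_cnn(pd, train_config(epochs = 40, batch_size = 8, seed = 6))
  pred <- predict(m, sc$cube)
  expect_equal(mean(pred$labels[cbind(seeds$row, seeds$col)] == seeds$category), 1)
  # scores form a distribution at every pixel
  expect_lt(max(abs(apply(pred$scores, c(1, 2), sum) - 1)), 1e-10)
  # band-count mismatch is rejected
  other <- hsi_cube(array(1, c(5, 5, 3)))
  expect_error(predict(m, other), "bands")
  # a category absent from training is an error
  bad <- pd; bad$labels[] <- 1L; bad$labels[1] <- 3L
  expect_error(hsi_cnn(bad), "missing")
})
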