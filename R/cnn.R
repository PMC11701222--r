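#' Extract square patches around labelled pixels
#'
#' Each labelled pixel yields one `size x size x C` window centred on it;
#' scene borders are handled by mirror (reflect) padding so edge pixels get
#' full-size patches without zero artefacts. The centre pixel defines the
#' patch label.
#'
#' @param cube An [hsi_cube()].
#' @param pixels Data frame or matrix with columns (row, col) and
#'   optionally `category`/`label`.
#' @param size Odd patch edge length (reference setting: 9).
#' @return A list of class `patch_dataset`: `patches` (`n x size^2 x C`
#'   array, spatial positions column-major), `labels`, `pixels`, `size`.
#' @export
extract_patches <- function(cube, pixels, size = 9L) {
  if (size %% 2L == 0L) stop("patch size must be odd, got ", size)
  d <- dim(cube)
  H <- d[1]; W <- d[2]; C <- d[3]
  r <- (size - 1L) %/% 2L
  if (H < r + 1L || W < r + 1L) stop("scene too small for mirror padding of width ", r)
  px <- as.data.frame(pixels)
  lab <- if ("category" %in% names(px)) px$category else px$label
  rows <- as.integer(px$row); cols <- as.integer(px$col)
  stopifnot(all(rows >= 1L & rows <= H), all(cols >= 1L & cols <= W))

  ridx <- c(rev(seq_len(r)), seq_len(H), H - seq_len(r) + 1L)
  cidx <- c(rev(seq_len(r)), seq_len(W), W - seq_len(r) + 1L)
  P <- unclass(cube)[ridx, cidx, , drop = FALSE]
  Pm <- matrix(P, (H + 2L * r) * (W + 2L * r), C)
  n <- length(rows)
  X <- array(0, c(n, size * size, C))
  Hp <- H + 2L * r
  for (dc in 0:(size - 1L)) {
    for (dr in 0:(size - 1L)) {
      s <- dc * size + dr + 1L
      lin <- (cols + dc - 1L) * Hp + rows + dr
      X[, s, ] <- Pm[lin, ]
    }
  }
  structure(list(patches = X, labels = if (is.null(lab)) NULL else as.integer(lab),
                 pixels = data.frame(row = rows, col = cols), size = size),
            class = "patch_dataset")
}

#' Merge seed labels and pseudo-labels into one training label set
#'
#' The union of the ground-truth seeds and the ledger of admitted
#' pseudo-labels. If a pixel somehow appears in both, the ground-truth seed
#' label wins and the conflict is reported.
#'
#' @param seeds `seed_labels` data frame.
#' @param pseudo Pseudo-label ledger (`row`, `col`, `category`) or an
#'   `ipg` fit; `NULL` for the seeds-only baseline.
#' @return Data frame with `row`, `col`, `category`, `source`.
#' @export
build_training_set <- function(seeds, pseudo = NULL) {
  out <- data.frame(row = seeds$row, col = seeds$col,
                    category = seeds$category, source = "seed")
  if (inherits(pseudo, "ipg")) pseudo <- pseudo$ledger
  if (!is.null(pseudo) && nrow(pseudo)) {
    ps <- data.frame(row = pseudo$row, col = pseudo$col,
                     category = pseudo$category, source = "pseudo")
    dup <- paste(ps$row, ps$col) %in% paste(out$row, out$col)
    if (any(dup)) {
      message(sum(dup), " pseudo-label(s) conflict with seed pixels; seeds kept")
      ps <- ps[!dup, , drop = FALSE]
    }
    out <- rbind(out, ps)
  }
  rownames(out) <- NULL
  out
}

#' Training configuration for the patch classifier
#'
#' Stochastic gradient descent with momentum and weight decay; the
#' reference optimiser setting is learning rate 0.05, momentum 0.7, weight
#' decay 1e-4.
#'
#' @param lr,momentum,weight_decay SGD hyperparameters.
#' @param epochs,batch_size Training schedule.
#' @param widths Feature widths of the two convolution blocks.
#' @param seed Integer seed (initialisation and batch shuffling).
#' @return A list of class `train_config`.
#' @export
train_config <- function(lr = 0.05, momentum = 0.7, weight_decay = 1e-4,
                         epochs = 100L, batch_size = 64L, widths = c(32L, 64L),
                         seed = 1L) {
  stopifnot(lr >= 0, momentum >= 0, momentum < 1, weight_decay >= 0,
            epochs >= 1L, batch_size >= 1L, length(widths) == 2L, all(widths >= 1L))
  structure(list(lr = lr, momentum = momentum, weight_decay = weight_decay,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 widths = as.integer(widths), seed = as.integer(seed)),
            class = "train_config")
}

# 3x3 same-padding convolution source map: S x 9 spatial indices (NA = pad)
conv_map3 <- function(h, w) {
  S <- h * w
  rr <- ((seq_len(S) - 1L) %% h) + 1L
  cc <- ((seq_len(S) - 1L) %/% h) + 1L
  m <- matrix(NA_integer_, S, 9L)
  k <- 0L
  for (dc in -1:1) for (dr in -1:1) {
    k <- k + 1L
    r2 <- rr + dr; c2 <- cc + dc
    ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
    m[ok, k] <- (c2[ok] - 1L) * h + r2[ok]
  }
  m
}

# 2x2 stride-2 max-pool source map: S' x 4 (odd trailing row/col dropped)
pool_map2 <- function(h, w) {
  ho <- h %/% 2L; wo <- w %/% 2L
  So <- ho * wo
  ro <- ((seq_len(So) - 1L) %% ho) + 1L
  co <- ((seq_len(So) - 1L) %/% ho) + 1L
  m <- matrix(NA_integer_, So, 4L)
  k <- 0L
  for (dc in 0:1) for (dr in 0:1) {
    k <- k + 1L
    m[, k] <- (2L * (co - 1L) + dc) * h + 2L * (ro - 1L) + dr + 1L
  }
  list(map = m, h = ho, w = wo)
}

# gather im2col columns: X [n, S, Cin] -> matrix (n*S) x (9*Cin)
im2col <- function(X, cmap) {
  n <- dim(X)[1]; S <- dim(X)[2]; Cin <- dim(X)[3]
  out <- matrix(0, n * S, 9L * Cin)
  for (k in 1:9) {
    src <- cmap[, k]
    ok <- !is.na(src)
    blk <- array(0, c(n, S, Cin))
    blk[, ok, ] <- X[, src[ok], , drop = FALSE]
    dim(blk) <- c(n * S, Cin)
    out[, ((k - 1L) * Cin + 1L):(k * Cin)] <- blk
  }
  out
}

# scatter-add the im2col gradient back onto the input grid
col2im <- function(dcols, cmap, n, S, Cin) {
  dX <- array(0, c(n, S, Cin))
  for (k in 1:9) {
    src <- cmap[, k]
    ok <- !is.na(src)
    blk <- dcols[, ((k - 1L) * Cin + 1L):(k * Cin), drop = FALSE]
    dim(blk) <- c(n, S, Cin)
    dX[, src[ok], ] <- dX[, src[ok], , drop = FALSE] + blk[, ok, , drop = FALSE]
  }
  dX
}

maxpool_forward <- function(Z, pmap) {
  n <- dim(Z)[1]; F <- dim(Z)[3]
  So <- nrow(pmap$map)
  out <- array(-Inf, c(n, So, F))
  arg <- array(1L, c(n, So, F))
  for (k in 1:4) {
    cand <- Z[, pmap$map[, k], , drop = FALSE]
    upd <- cand > out
    out[upd] <- cand[upd]
    arg[upd] <- k
  }
  list(out = out, arg = arg)
}

maxpool_backward <- function(dout, arg, pmap, S) {
  n <- dim(dout)[1]; F <- dim(dout)[3]
  dZ <- array(0, c(n, S, F))
  for (k in 1:4) {
    sel <- arg == k
    if (!any(sel)) next
    d <- dout
    d[!sel] <- 0
    dZ[, pmap$map[, k], ] <- dZ[, pmap$map[, k], , drop = FALSE] + d
  }
  dZ
}

cnn_forward <- function(par, X, geom, want_cache = FALSE) {
  n <- dim(X)[1]
  cols1 <- im2col(X, geom$cmap1)
  Z1 <- cols1 %*% par$W1
  Z1 <- sweep(Z1, 2L, par$b1, "+")
  A1 <- pmax(Z1, 0)
  A1a <- array(A1, c(n, geom$S1, ncol(par$W1)))
  P1 <- maxpool_forward(A1a, geom$pmap1)

  cols2 <- im2col(P1$out, geom$cmap2)
  Z2 <- cols2 %*% par$W2
  Z2 <- sweep(Z2, 2L, par$b2, "+")
  A2 <- pmax(Z2, 0)
  A2a <- array(A2, c(n, geom$S2, ncol(par$W2)))
  P2 <- maxpool_forward(A2a, geom$pmap2)

  G <- colMeans(aperm(P2$out, c(2, 1, 3)))          # n x F2, mean over space
  if (is.null(dim(G))) G <- matrix(G, nrow = n)
  logits <- sweep(G %*% par$W3, 2L, par$b3, "+")
  res <- list(logits = logits)
  if (want_cache) {
    res$cache <- list(X = X, cols1 = cols1, Z1 = Z1, P1 = P1,
                      cols2 = cols2, Z2 = Z2, P2 = P2, G = G)
  }
  res
}

cnn_backward <- function(par, geom, cache, dlogits) {
  n <- nrow(dlogits)
  F1 <- ncol(par$W1); F2 <- ncol(par$W2)
  grads <- list()
  grads$W3 <- t(cache$G) %*% dlogits
  grads$b3 <- colSums(dlogits)
  dG <- dlogits %*% t(par$W3)                       # n x F2
  So2 <- nrow(geom$pmap2$map)
  dP2 <- array(rep(dG / So2, each = 1), c(n, 1L, F2))[, rep(1L, So2), , drop = FALSE]
  dA2 <- maxpool_backward(dP2, cache$P2$arg, geom$pmap2, geom$S2)
  dZ2 <- dA2
  dZ2[array(cache$Z2, dim(dA2)) <= 0] <- 0
  dZ2m <- matrix(dZ2, n * geom$S2, F2)
  grads$W2 <- t(cache$cols2) %*% dZ2m
  grads$b2 <- colSums(dZ2m)
  dcols2 <- dZ2m %*% t(par$W2)
  dP1 <- col2im(dcols2, geom$cmap2, n, nrow(geom$pmap1$map), F1)
  dA1 <- maxpool_backward(dP1, cache$P1$arg, geom$pmap1, geom$S1)
  dZ1 <- dA1
  dZ1[array(cache$Z1, dim(dA1)) <= 0] <- 0
  dZ1m <- matrix(dZ1, n * geom$S1, F1)
  grads$W1 <- t(cache$cols1) %*% dZ1m
  grads$b1 <- colSums(dZ1m)
  grads
}

cnn_geometry <- function(size) {
  S1 <- size * size
  pmap1 <- pool_map2(size, size)
  S2 <- pmap1$h * pmap1$w
  pmap2 <- pool_map2(pmap1$h, pmap1$w)
  if (nrow(pmap2$map) < 1L) stop("patch size too small for two pooling stages")
  list(cmap1 = conv_map3(size, size), S1 = S1, pmap1 = pmap1,
       cmap2 = conv_map3(pmap1$h, pmap1$w), S2 = S2, pmap2 = pmap2)
}

#' Train the patch-based 2D convolutional classifier
#'
#' A deliberately small network: two 3x3 convolution blocks (feature widths
#' 32 and 64, ReLU, 2x2 max pooling) followed by global average pooling and
#' a linear softmax head, trained with SGD (momentum, weight decay) on
#' cross-entropy. Implemented in vectorised base R via im2col convolutions
#' with analytic backpropagation; training is deterministic for a given
#' seed.
#'
#' @param data A [extract_patches()] dataset with labels for every patch.
#' @param config A [train_config()].
#' @return An object of class `hsi_cnn` with the fitted parameters, the
#'   per-epoch training loss, and the training configuration.
#' @export
hsi_cnn <- function(data, config = train_config()) {
  stopifnot(inherits(data, "patch_dataset"), !is.null(data$labels))
  X <- data$patches
  y <- data$labels
  K <- max(y)
  if (any(tabulate(y, K) == 0L)) {
    stop("every category needs at least one training patch; missing: ",
         paste(which(tabulate(y, K) == 0L), collapse = ", "))
  }
  n <- dim(X)[1]; Cin <- dim(X)[3]
  geom <- cnn_geometry(data$size)
  F1 <- config$widths[1]; F2 <- config$widths[2]

  with_seed(derive_seed(config$seed, "cnn"), {
    par <- list(
      W1 = matrix(stats::rnorm(9L * Cin * F1, sd = sqrt(2 / (9 * Cin))), 9L * Cin, F1),
      b1 = rep(0, F1),
      W2 = matrix(stats::rnorm(9L * F1 * F2, sd = sqrt(2 / (9 * F1))), 9L * F1, F2),
      b2 = rep(0, F2),
      W3 = matrix(stats::rnorm(F2 * K, sd = sqrt(2 / F2)), F2, K),
      b3 = rep(0, K))
    vel <- lapply(par, function(p) p * 0)
    onehot <- matrix(0, n, K)
    onehot[cbind(seq_len(n), y)] <- 1
    losses <- numeric(config$epochs)
    decayed <- c("W1", "W2", "W3")   # weight decay on weights, not biases

    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = config$batch_size)) {
        bi <- ord[start:min(start + config$batch_size - 1L, n)]
        fwd <- cnn_forward(par, X[bi, , , drop = FALSE], geom, want_cache = TRUE)
        lg <- fwd$logits
        lse <- log(rowSums(exp(lg - apply(lg, 1L, max)))) + apply(lg, 1L, max)
        prob <- exp(lg - lse)
        ep_loss <- ep_loss + sum(lse - lg[cbind(seq_along(bi), y[bi])])
        dlogits <- (prob - onehot[bi, , drop = FALSE]) / length(bi)
        grads <- cnn_backward(par, geom, fwd$cache, dlogits)
        for (nm in names(par)) {
          g <- grads[[nm]]
          if (nm %in% decayed) g <- g + config$weight_decay * par[[nm]]
          vel[[nm]] <- config$momentum * vel[[nm]] - config$lr * g
          par[[nm]] <- par[[nm]] + vel[[nm]]
        }
      }
      losses[ep] <- ep_loss / n
    }
    structure(list(par = par, geom = geom, size = data$size, n_bands = Cin,
                   n_classes = K, loss = losses, config = config),
              class = "hsi_cnn")
  })
}

#' @export
print.hsi_cnn <- function(x, ...) {
  cat(sprintf("<hsi_cnn> %dx%d patches, %d bands -> %d classes; %d epochs, final loss %.4f\n",
              x$size, x$size, x$n_bands, x$n_classes,
              length(x$loss), utils::tail(x$loss, 1)))
  invisible(x)
}

#' Predict a full classification map
#'
#' Every pixel of the cube is classified from its mirror-padded patch; the
#' per-pixel class scores are a proper softmax distribution.
#'
#' @param object A fitted [hsi_cnn()].
#' @param cube An [hsi_cube()] with the same band count as training.
#' @param chunk Pixels per forward batch (memory control).
#' @param ... Unused.
#' @return A list of class `prediction_map`: `labels` ([label_map()],
#'   every pixel assigned) and `scores` (`H x W x K`, rows sum to 1).
#' @export
predict.hsi_cnn <- function(object, cube, chunk = 512L, ...) {
  d <- dim(cube)
  if (d[3] != object$n_bands) {
    stop("cube has ", d[3], " bands but the model was trained on ", object$n_bands)
  }
  H <- d[1]; W <- d[2]; K <- object$n_classes
  all_px <- data.frame(row = rep(seq_len(H), W), col = rep(seq_len(W), each = H))
  scores <- matrix(0, H * W, K)
  for (start in seq(1L, H * W, by = chunk)) {
    idx <- start:min(start + chunk - 1L, H * W)
    pd <- extract_patches(cube, all_px[idx, ], object$size)
    lg <- cnn_forward(object$par, pd$patches, object$geom)$logits
    mx <- apply(lg, 1L, max)
    pr <- exp(lg - mx)
    scores[idx, ] <- pr / rowSums(pr)
  }
  lab <- max.col(scores, ties.method = "first")
  structure(list(labels = label_map(matrix(as.integer(lab), H, W), K),
                 scores = array(scores, c(H, W, K))),
            class = "prediction_map")
}

#' @export
print.prediction_map <- function(x, ...) {
  cat(sprintf("<prediction_map> %d x %d pixels, %d classes\n",
              nrow(x$labels), ncol(x$labels), attr(x$labels, "n_classes")))
  invisible(x)
}
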