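#' Cosine similarity between feature vectors
#'
#' @param f_a,f_b Numeric vectors of equal length; both must have nonzero
#'   norm.
#' @return `<f_a, f_b> / (||f_a|| ||f_b||)`, in `[-1, 1]`.
#' @export
cosine_sim <- function(f_a, f_b) {
  stopifnot(length(f_a) == length(f_b))
  na <- sqrt(sum(f_a^2)); nb <- sqrt(sum(f_b^2))
  if (na == 0 || nb == 0) stop("cosine similarity is undefined for a zero vector")
  min(max(sum(f_a * f_b) / (na * nb), -1), 1)
}

# row-normalise a matrix of feature vectors; errors on zero rows
row_unit <- function(M, what = "feature") {
  n <- sqrt(rowSums(M^2))
  if (any(n == 0)) stop("zero-norm ", what, " vector")
  M / n
}

#' Similarity-based confidence of a pixel against a prompt set
#'
#' The confidence of pixel feature `f_a` for category `i` is the arithmetic
#' mean of its cosine similarities to the `n` features of that category's
#' current prompt points. The companion uncertainty is the population
#' variance of those same `n` similarities: a pixel that agrees strongly
#' with some prompts and weakly with others is treated as unreliable even
#' if its mean similarity is high.
#'
#' @param f_a Numeric feature vector of the pixel.
#' @param F_i Numeric matrix, one prompt feature per row (`n >= 1`).
#' @return `prompt_confidence()` the mean similarity `p` in `[-1, 1]`;
#'   `prompt_uncertainty()` the variance `u >= 0` (0 when `n = 1`).
#' @export
prompt_confidence <- function(f_a, F_i) {
  s <- similarity_vector(f_a, F_i)
  mean(s)
}

#' @rdname prompt_confidence
#' @export
prompt_uncertainty <- function(f_a, F_i) {
  s <- similarity_vector(f_a, F_i)
  mean((s - mean(s))^2)
}

similarity_vector <- function(f_a, F_i) {
  if (is.null(dim(F_i))) F_i <- matrix(F_i, nrow = 1L)
  if (nrow(F_i) < 1L) stop("empty prompt feature set")
  na <- sqrt(sum(f_a^2))
  if (na == 0) stop("zero-norm feature vector")
  drop(row_unit(F_i, "prompt feature") %*% (f_a / na))
}

#' Selection thresholds for pseudo-labels
#'
#' `tau_h` and `tau_l` split the confidence axis into foreground
#' (`p >= tau_h`), background (`p <= tau_l`) and an abstain band between;
#' `kappa_h` bounds the admissible uncertainty of a positive pseudo-label.
#' Defaults are the reference setting `tau_h = 0.8`, `tau_l = 0.5`,
#' `kappa_h = 0.2`.
#'
#' @param tau_h,tau_l Confidence thresholds, `0 <= tau_l < tau_h <= 1`.
#' @param kappa_h Uncertainty threshold, `> 0`.
#' @return A list of class `thresholds`.
#' @export
thresholds <- function(tau_h = 0.8, tau_l = 0.5, kappa_h = 0.2) {
  stopifnot(tau_l >= 0, tau_l < tau_h, tau_h <= 1, kappa_h > 0)
  structure(list(tau_h = tau_h, tau_l = tau_l, kappa_h = kappa_h),
            class = "thresholds")
}

#' Three-way confidence thresholding
#'
#' @param p Confidence value(s).
#' @param t A [thresholds()].
#' @return `+1` (foreground) where `p >= tau_h`, `-1` (background) where
#'   `p <= tau_l`, `0` (abstain) in the open band between. Vectorised.
#' @export
threshold_label <- function(p, t = thresholds()) {
  stopifnot(inherits(t, "thresholds"))
  ifelse(p >= t$tau_h, 1L, ifelse(p <= t$tau_l, -1L, 0L))
}

#' Pseudo-label selection gate
#'
#' A pixel's pseudo-label enters training only when both indicators hold:
#' confidence at least `tau_h` and uncertainty at most `kappa_h`. Gated
#' pixels are admitted as hard (weight-1) labels; the stored confidence is
#' not overwritten.
#'
#' @param p Confidence value(s).
#' @param u Uncertainty value(s).
#' @param t A [thresholds()].
#' @return 0/1 integer gate, vectorised.
#' @export
selection_gate <- function(p, u, t = thresholds()) {
  stopifnot(inherits(t, "thresholds"))
  as.integer(u <= t$kappa_h & p >= t$tau_h)
}

#' Spatial-information-consistency loss
#'
#' For category `i`, gated pixels should look like category `i`'s prompts
#' (high `p^(i)`) and unlike every other category's prompts (low `p^(j)`).
#' The loss is the negated binary-classification log-likelihood
#' `-(sum over gated pixels a) [log p_a^(i) + sum_{j != i} log(1 - p_a^(j))]`;
#' pixels whose gate is 0 contribute nothing, and confidences are clipped
#' into `[eps, 1 - eps]` before the logarithms (mean cosines can fall
#' outside `(0, 1)`). Lower is better; 0 is the perfect-separation
#' infimum.
#'
#' @param p Numeric matrix, rows = pixels, columns = the `K` per-category
#'   confidences; `K >= 2`.
#' @param gate 0/1 vector, one entry per pixel (row of `p`).
#' @param i Category index the pixels were gated for.
#' @param eps Clipping constant.
#' @return Nonnegative scalar loss.
#' @export
consistency_loss <- function(p, gate, i, eps = 1e-7) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
  K <- ncol(p)
  if (K < 2L) stop("consistency loss needs K >= 2 categories")
  stopifnot(length(gate) == nrow(p), i >= 1L, i <= K)
  pc <- pmin(pmax(p, eps), 1 - eps)
  per_pixel <- log(pc[, i]) + rowSums(log(1 - pc[, -i, drop = FALSE]))
  -sum(gate * per_pixel)
}

# Loss and its analytic gradient w.r.t. the D x D projection A.
#
# X: pixel features (rows), prompt_feats: list over categories of prompt
# feature matrices, gate/cat_i: per-pixel gate and gated category. All
# similarities are cosines between projected vectors, S = cos(A x, A w);
# p^(j)(a) = mean_m S(a, w_jm). Gradient flows through both arguments of
# the cosine. Clipped confidences get zero gradient. Verified against
# numerical differentiation in the test suite.
consistency_loss_grad <- function(A, X, prompt_feats, gate, cat_i, eps = 1e-7) {
  K <- length(prompt_feats)
  D <- ncol(A)
  keep <- gate == 1L
  if (!any(keep)) return(list(loss = 0, grad = matrix(0, D, D)))
  X <- X[keep, , drop = FALSE]
  cat_i <- cat_i[keep]
  n_pix <- nrow(X)

  U <- X %*% t(A)                      # projected pixel features
  nu <- sqrt(rowSums(U^2))
  if (any(nu == 0)) stop("zero-norm projected pixel feature")
  Un <- U / nu

  P <- matrix(0, n_pix, K)
  Slist <- vector("list", K)
  Vlist <- vector("list", K)
  for (j in seq_len(K)) {
    Wf <- prompt_feats[[j]]
    V <- Wf %*% t(A)
    nv <- sqrt(rowSums(V^2))
    if (any(nv == 0)) stop("zero-norm projected prompt feature")
    S <- Un %*% t(V / nv)              # n_pix x n_j cosines
    Slist[[j]] <- S
    Vlist[[j]] <- V
    P[, j] <- rowMeans(S)
  }
  Pc <- pmin(pmax(P, eps), 1 - eps)
  own <- cbind(seq_len(n_pix), cat_i)
  loss <- -(sum(log(Pc[own])) + sum(log(1 - Pc)) - sum(log(1 - Pc[own])))

  # dL/dP: -1/p for the own category, +1/(1-p) for the others; zero where
  # clipping is active
  dLdP <- 1 / (1 - Pc)
  dLdP[own] <- -1 / Pc[own]
  dLdP[P < eps | P > 1 - eps] <- 0

  grad <- matrix(0, D, D)
  for (j in seq_len(K)) {
    Wf <- prompt_feats[[j]]
    n_j <- nrow(Wf)
    V <- Vlist[[j]]
    nv <- sqrt(rowSums(V^2))
    Vn <- V / nv
    S <- Slist[[j]]
    Cw <- dLdP[, j] / n_j              # weight on each S_am, m = 1..n_j
    # dS/du term, summed over prompts m:
    #   sum_m c_am [ vhat_m / |u_a| - S_am uhat_a / |u_a| ]
    Gu <- ((matrix(Cw, n_pix, n_j) %*% Vn) - rowSums(S * Cw) * Un) / nu
    grad <- grad + t(Gu) %*% X
    # dS/dv term, summed over pixels a:
    #   sum_a c_am [ uhat_a / |v_m| - S_am vhat_m / |v_m| ]
    su <- colSums(Cw * Un)             # sum_a c_a uhat_a, shared by all m
    Gv <- (matrix(su, n_j, D, byrow = TRUE) - Vn * colSums(S * Cw)) / nv
    grad <- grad + t(Gv) %*% Wf
  }
  list(loss = loss, grad = grad)
}
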