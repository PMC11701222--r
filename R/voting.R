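#' Spectral voting: tally per-group mask decisions
#'
#' Each of the `C - 2` band groups contributes one binary decision per
#' pixel and category, so every pixel undergoes `C - 2` predictions for
#' every category; the tally `T(a, i)` counts the positive ones. Fusing the
#' redundant per-group masks this way suppresses the category confusion
#' that any single three-band rendering suffers.
#'
#' @param stack Logical or 0/1 array of dimension `G x K x H x W`
#'   (group, category, row, col) — the full mask stack.
#' @return Integer array `K x H x W` of class `vote_tally`;
#'   `0 <= T(a, i) <= G`.
#' @export
vote_tally <- function(stack) {
  d <- dim(stack)
  if (is.null(d) || length(d) != 4L) stop("mask stack must be a G x K x H x W array")
  v <- as.numeric(stack)
  if (any(is.na(v)) || any(v != 0 & v != 1)) stop("mask stack must be binary")
  G <- d[1]
  counts <- colSums(array(v, c(G, prod(d[-1]))))
  structure(array(as.integer(counts), d[-1]),
            class = "vote_tally", n_groups = G)
}

#' Assign each pixel the category with the most votes
#'
#' The label is `argmax_i T(a, i)` provided the winning count reaches
#' `min_votes`; ties break toward the smallest category index, and pixels
#' whose best count is below `min_votes` (in particular all-zero tallies)
#' stay unassigned (label 0). The margin between the top two counts is
#' recorded per pixel as a fusion-confidence diagnostic.
#'
#' @param tally A [vote_tally()] (`K x H x W`).
#' @param min_votes Minimum winning vote count for assignment (>= 1).
#' @return A list of class `voted_map`: `labels` ([label_map()], 0 =
#'   unassigned) and `margin` (integer matrix, top-1 minus top-2 count;
#'   for `K = 1` the margin is the count itself).
#' @export
vote_assign <- function(tally, min_votes = 1L) {
  stopifnot(min_votes >= 1L)
  d <- dim(tally)
  if (is.null(d) || length(d) != 3L) stop("tally must be a K x H x W array")
  K <- d[1]; H <- d[2]; W <- d[3]
  m <- matrix(as.numeric(tally), nrow = K)   # K x (H*W)
  best <- max.col(t(m), ties.method = "first")
  top1 <- m[cbind(best, seq_len(H * W))]
  if (K > 1L) {
    m2 <- m
    m2[cbind(best, seq_len(H * W))] <- -Inf
    top2 <- apply(m2, 2L, max)
  } else {
    top2 <- rep(0, H * W)
  }
  lab <- ifelse(top1 >= min_votes, best, 0L)
  structure(list(labels = label_map(matrix(as.integer(lab), H, W), K),
                 margin = matrix(as.integer(top1 - top2), H, W)),
            class = "voted_map")
}

#' @export
print.voted_map <- function(x, ...) {
  n <- sum(x$labels > 0L)
  cat(sprintf("<voted_map> %d x %d, %d/%d pixels assigned over %d categories\n",
              nrow(x$labels), ncol(x$labels), n, length(x$labels),
              attr(x$labels, "n_classes")))
  invisible(x)
}
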