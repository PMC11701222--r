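#' Derive a stage-specific random seed from a global seed
#'
#' A single user-facing seed fans out to independent per-stage seeds so that
#' stages are individually reproducible without manual seed bookkeeping.
#' The derivation is a stable polynomial hash of the stage name folded into
#' the global seed, kept inside the 32-bit integer range.
#'
#' @param seed Global integer seed.
#' @param stage Character stage name, e.g. `"scene"`, `"seeds"`, `"ipg"`.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (v in utf8ToInt(stage)) h <- (h * 31 + v) %% 2147483647
  as.integer((abs(as.numeric(seed)) %% 2147483647 * 131 + h) %% 2147483647)
}

# run expr with a local RNG state; restores (or clears) .Random.seed after
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# shift a matrix by (dr, dc), padding the vacated rows/cols with `fill`
shift_matrix <- function(m, dr, dc, fill = FALSE) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  rsrc <- seq_len(H) - dr
  csrc <- seq_len(W) - dc
  rok <- rsrc >= 1L & rsrc <= H
  cok <- csrc >= 1L & csrc <= W
  out[rok, cok] <- m[rsrc[rok], csrc[cok]]
  out
}

# one step of 4-connected binary dilation
dilate4 <- function(m) {
  m | shift_matrix(m, 1L, 0L) | shift_matrix(m, -1L, 0L) |
    shift_matrix(m, 0L, 1L) | shift_matrix(m, 0L, -1L)
}

# pixels within `width` 4-connected steps of the boundary of binary mask `m`
# (on either side); the set where segmentation errors are plausible
boundary_band <- function(m, width) {
  if (width <= 0L) return(matrix(FALSE, nrow(m), ncol(m)))
  grown <- m
  shrunk <- m
  for (i in seq_len(width)) {
    grown <- dilate4(grown)
    shrunk <- !dilate4(!shrunk)
  }
  grown & !shrunk
}
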