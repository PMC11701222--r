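#' Point prompts
#'
#' A prompt is a pixel coordinate tagged foreground or background; a set of
#' prompts conditions one category's mask prediction. Provenance records
#' whether a prompt is an original seed label or a pseudo-label admitted at
#' some iteration.
#'
#' @param row,col Integer pixel coordinates.
#' @param polarity `"foreground"` or `"background"` (recycled).
#' @param provenance Free-form origin tag, e.g. `"seed"` or `"pseudo@12"`.
#' @return A `data.frame` of class `point_prompts`.
#' @export
point_prompts <- function(row, col, polarity = "foreground", provenance = "seed") {
  polarity <- match.arg(polarity, c("foreground", "background"), several.ok = TRUE)
  out <- data.frame(row = as.integer(row), col = as.integer(col),
                    polarity = rep_len(polarity, length(row)),
                    provenance = rep_len(provenance, length(row)))
  class(out) <- c("point_prompts", "data.frame")
  out
}

#' Promptable segmenter backends
#'
#' A backend answers two questions: given a three-channel image and point
#' prompts for one category, what is that category's mask ([segment()])?
#' And what per-pixel feature vectors does the image induce
#' ([embed_features()])? The shipped backend is a synthetic oracle that
#' derives masks from a known ground truth with a controllable noise model,
#' which makes every downstream stage testable without pretrained weights.
#' An adapter to a pretrained foundation segmenter satisfies the same
#' contract (mask from prompts, encoder activations resampled to the pixel
#' grid) and can be dropped in without touching the rest of the pipeline.
#'
#' @param bundle An `oracle_bundle` from [export_oracle()].
#' @return `oracle_segmenter()` returns an object of class
#'   `c("oracle_segmenter", "segmenter")`.
#' @export
oracle_segmenter <- function(bundle) {
  stopifnot(inherits(bundle, "oracle_bundle"))
  structure(list(bundle = bundle), class = c("oracle_segmenter", "segmenter"))
}

#' @export
print.oracle_segmenter <- function(x, ...) {
  b <- x$bundle
  cat(sprintf("<oracle_segmenter> %dx%d truth, flip rate %.2f in band width %d, dilate %d\n",
              nrow(b$truth), ncol(b$truth), b$flip_rate, b$band_width, b$dilate))
  invisible(x)
}

#' Segment one category from point prompts
#'
#' @param backend A `segmenter` backend.
#' @param image3 `H x W x 3` image (a normalised band group).
#' @param prompts [point_prompts()] for one category; at least one
#'   foreground prompt is required.
#' @param group Band-group index, used by the oracle to key its
#'   deterministic per-group noise draw.
#' @return A list of class `segmentation` with `mask` (logical `H x W`),
#'   `score` (numeric in `[0, 1]`, `mask == (score >= 0.5)`) and the
#'   category the backend inferred from the prompts.
#' @export
segment <- function(backend, image3, prompts, group = 1L) {
  UseMethod("segment")
}

#' @export
segment.oracle_segmenter <- function(backend, image3, prompts, group = 1L) {
  b <- backend$bundle
  H <- nrow(b$truth); W <- ncol(b$truth)
  check_prompts(prompts, H, W)
  fg <- prompts[prompts$polarity == "foreground", , drop = FALSE]
  # the oracle reads the prompted category off the ground truth: majority
  # truth label under the foreground points, smallest label on ties
  lab <- b$truth[cbind(fg$row, fg$col)]
  lab <- lab[lab > 0L]
  if (!length(lab)) stop("foreground prompts fall only on unlabelled pixels")
  cat_i <- as.integer(which.max(tabulate(lab)))
  mask <- unclass(b$truth) == cat_i
  if (b$flip_rate > 0 && b$band_width > 0L) {
    elig <- which(boundary_band(mask, b$band_width))
    if (length(elig)) {
      flips <- with_seed(
        derive_seed(b$seed, sprintf("oracle-mask-g%d-k%d", group, cat_i)),
        stats::runif(length(elig)) < b$flip_rate
      )
      mask[elig[flips]] <- !mask[elig[flips]]
    }
  }
  if (b$dilate > 0L) for (i in seq_len(b$dilate)) mask <- dilate4(mask)
  structure(list(mask = mask, score = mask + 0, category = cat_i),
            class = "segmentation")
}

#' Per-pixel feature field of an image
#'
#' @inheritParams segment
#' @return An `H x W x D` numeric array with attribute `source`
#'   (`"oracle"` for the synthetic backend). The oracle emits each pixel's
#'   observed spectrum — class signature plus scene noise — so at zero
#'   noise all pixels of one class share an identical vector.
#' @export
embed_features <- function(backend, image3 = NULL) {
  UseMethod("embed_features")
}

#' @export
embed_features.oracle_segmenter <- function(backend, image3 = NULL) {
  structure(backend$bundle$embeddings, source = "oracle")
}

check_prompts <- function(prompts, H, W) {
  if (!is.data.frame(prompts) || !all(c("row", "col", "polarity") %in% names(prompts))) {
    stop("prompts must be a point_prompts data frame")
  }
  if (!any(prompts$polarity == "foreground")) {
    stop("at least one foreground prompt is required")
  }
  if (any(prompts$row < 1L | prompts$row > H | prompts$col < 1L | prompts$col > W)) {
    stop("prompt coordinates out of image bounds")
  }
  invisible(TRUE)
}

#' Trainable prompt-feature projection
#'
#' All backend parameters are frozen except one `D x D` linear map applied
#' to feature vectors before similarities are computed; this is the only
#' part of the prompt pathway that trains, via gradient steps on the
#' spatial-information-consistency loss.
#'
#' @param D Feature dimension.
#' @return Identity-initialised `D x D` matrix of class `prompt_projection`.
#' @export
prompt_projection <- function(D) {
  stopifnot(D >= 2)
  structure(diag(D), class = c("prompt_projection", "matrix"))
}

#' Apply one gradient step to the prompt projection
#'
#' @param proj A [prompt_projection()].
#' @param grad Gradient of the loss w.r.t. the projection (`D x D`).
#' @param lr Positive learning rate.
#' @return The updated projection. A non-finite gradient skips the step
#'   with a warning; a zero gradient or zero learning rate leaves the
#'   projection unchanged.
#' @export
projection_step <- function(proj, grad, lr) {
  stopifnot(identical(dim(proj), dim(grad)), lr >= 0)
  if (any(!is.finite(grad))) {
    warning("non-finite gradient; projection step skipped")
    return(proj)
  }
  out <- unclass(proj) - lr * grad
  class(out) <- class(proj)
  out
}
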