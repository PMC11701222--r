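#' Configuration of the iterative pseudo-label generation loop
#'
#' @param iterations Number of refinement iterations (reference setting:
#'   50; accuracy degrades well past that as pseudo-labels collapse onto
#'   the labelled set).
#' @param selections_per_class Pseudo-labels admitted per category per
#'   iteration (reference setting: 1).
#' @param thresholds A [thresholds()] object (`tau_h`, `tau_l`,
#'   `kappa_h`).
#' @param min_votes Minimum winning vote count for the voted map.
#' @param lr Learning rate of the prompt-projection gradient step.
#' @param grad_clip Cap on the Frobenius norm of the projection gradient
#'   (stabilises the step across scene sizes); `Inf` disables.
#' @param seed Integer seed for any stochastic stage.
#' @return A list of class `ipg_config`.
#' @export
ipg_config <- function(iterations = 50L, selections_per_class = 1L,
                       thresholds = ipghsi::thresholds(), min_votes = 1L,
                       lr = 0.01, grad_clip = 1, seed = 1L) {
  stopifnot(iterations >= 1L, selections_per_class >= 1L,
            inherits(thresholds, "thresholds"), min_votes >= 1L,
            lr >= 0, grad_clip > 0)
  structure(list(iterations = as.integer(iterations),
                 selections_per_class = as.integer(selections_per_class),
                 thresholds = thresholds, min_votes = as.integer(min_votes),
                 lr = lr, grad_clip = grad_clip, seed = as.integer(seed)),
            class = "ipg_config")
}

#' Initialise the iterative loop from seed labels
#'
#' One-vs-rest prompting: for each category `i`, `i`'s seed pixels are the
#' foreground prompts and every other category's seeds are the background
#' prompts. The pseudo-label ledger starts empty and the prompt-feature
#' projection starts at the identity.
#'
#' @param seeds A `seed_labels` data frame from [sample_seed_labels()].
#' @param D Feature dimension of the backend's embedding field.
#' @return A list of class `ipg_state`.
#' @export
ipg_initialize <- function(seeds, D) {
  K <- max(seeds$category)
  if (K < 2L) stop("one-vs-rest prompting needs K >= 2 categories")
  counts <- tabulate(seeds$category, K)
  if (any(counts == 0L)) {
    stop("no seeds for category ", paste(which(counts == 0L), collapse = ", "))
  }
  key <- paste(seeds$row, seeds$col)
  if (anyDuplicated(key)) stop("a seed pixel appears in more than one category")
  prompts <- lapply(seq_len(K), function(i) {
    own <- seeds[seeds$category == i, , drop = FALSE]
    oth <- seeds[seeds$category != i, , drop = FALSE]
    rbind(point_prompts(own$row, own$col, "foreground", "seed"),
          point_prompts(oth$row, oth$col, "background", "seed"))
  })
  structure(list(prompts = prompts,
                 ledger = empty_ledger(),
                 projection = prompt_projection(D),
                 seeds = seeds, K = K,
                 mask_cache = new.env(parent = emptyenv()),
                 iteration = 0L,
                 log = data.frame()),
            class = "ipg_state")
}

empty_ledger <- function() {
  data.frame(row = integer(), col = integer(), category = integer(),
             p = numeric(), u = numeric(), iteration = integer())
}

#' Run one refinement iteration
#'
#' One iteration performs, in order: (1) segment every band group for every
#' category with the current prompts into a mask stack; (2) fuse the stack
#' by spectral voting; (3) for each category, compute confidence and
#' uncertainty of every pixel the vote assigned to it (excluding existing
#' prompts and ledger entries), using projected features against the
#' category's current foreground-prompt features; (4) apply the selection
#' gate; (5) admit the top `selections_per_class` gated pixels per category
#' by confidence (ties in row-major pixel order; a pixel gated by two
#' categories goes to the higher confidence) as new foreground prompts and
#' ledger entries; (6) take one gradient step on the
#' spatial-information-consistency loss summed over categories, updating
#' only the prompt projection.
#'
#' @param state An `ipg_state`.
#' @param backend A `segmenter` backend.
#' @param groups Normalised band groups ([decompose_bands()] +
#'   [normalize_group()]), or `NULL` to let the oracle work from its
#'   bundle.
#' @param config An [ipg_config()].
#' @return The updated `ipg_state`.
#' @export
ipg_iterate <- function(state, backend, groups, config) {
  t_now <- state$iteration + 1L
  emb <- embed_features(backend)
  D <- dim(emb)[3]
  H <- dim(emb)[1]; W <- dim(emb)[2]
  emb_mat <- matrix(emb, H * W, D)
  n_groups <- length(groups)

  # (1) mask stack, G x K x H x W
  stack <- array(FALSE, c(n_groups, state$K, H, W))
  for (i in seq_len(state$K)) {
    masks <- category_masks(state, backend, groups, i)
    for (j in seq_len(n_groups)) stack[j, i, , ] <- masks[[j]]
  }
  # (2) spectral voting
  voted <- vote_assign(vote_tally(stack), config$min_votes)

  # (3)-(4) per-category confidence, uncertainty, gate
  A <- unclass(state$projection)
  blocked <- matrix(FALSE, H, W)
  blocked[cbind(state$seeds$row, state$seeds$col)] <- TRUE
  if (nrow(state$ledger)) blocked[cbind(state$ledger$row, state$ledger$col)] <- TRUE
  prompt_feats <- lapply(seq_len(state$K), function(i) {
    fg <- state$prompts[[i]]
    fg <- fg[fg$polarity == "foreground", , drop = FALSE]
    emb_mat[(fg$col - 1L) * H + fg$row, , drop = FALSE]
  })
  cand <- vector("list", state$K)
  for (i in seq_len(state$K)) {
    idx <- which(voted$labels == i & !blocked)
    if (!length(idx)) { cand[[i]] <- NULL; next }
    X <- emb_mat[idx, , drop = FALSE] %*% t(A)
    Pf <- row_unit(prompt_feats[[i]] %*% t(A), "projected prompt")
    S <- row_unit(X, "projected pixel") %*% t(Pf)
    p <- rowMeans(S)
    u <- rowMeans((S - p)^2)
    g <- selection_gate(p, u, config$thresholds)
    cand[[i]] <- data.frame(pix = idx, category = i, p = p, u = u, gate = g)
  }
  cand <- do.call(rbind, cand)

  # (5) selection: top gated candidates per category, conflicts to higher p
  added <- empty_ledger()
  if (!is.null(cand) && any(cand$gate == 1L)) {
    gated <- cand[cand$gate == 1L, , drop = FALSE]
    rr <- ((gated$pix - 1L) %% H) + 1L
    cc <- ((gated$pix - 1L) %/% H) + 1L
    picks <- unlist(lapply(split(seq_len(nrow(gated)), gated$category),
      function(rows) {
        o <- rows[order(-gated$p[rows], rr[rows], cc[rows])]
        utils::head(o, config$selections_per_class)
      }), use.names = FALSE)
    sel <- gated[picks, , drop = FALSE]
    # a pixel gated by two categories in one iteration: keep the higher p
    # (smaller category index on exact ties), skip the loser this round
    o <- order(-sel$p, sel$category)
    sel <- sel[o, , drop = FALSE]
    sel <- sel[!duplicated(sel$pix), , drop = FALSE]
    added <- data.frame(row = ((sel$pix - 1L) %% H) + 1L,
                        col = ((sel$pix - 1L) %/% H) + 1L,
                        category = sel$category, p = sel$p, u = sel$u,
                        iteration = t_now)
    for (i in unique(added$category)) {
      a <- added[added$category == i, , drop = FALSE]
      state$prompts[[i]] <- rbind(state$prompts[[i]],
        point_prompts(a$row, a$col, "foreground", sprintf("pseudo@%d", t_now)))
    }
    state$ledger <- rbind(state$ledger, added)
  }

  # (6) one projection step on the consistency loss over gated pixels
  loss <- 0
  if (!is.null(cand) && any(cand$gate == 1L) && config$lr > 0) {
    gated <- cand[cand$gate == 1L, , drop = FALSE]
    lg <- consistency_loss_grad(A, emb_mat[gated$pix, , drop = FALSE],
                                prompt_feats, rep(1L, nrow(gated)),
                                gated$category)
    loss <- lg$loss
    gnorm <- sqrt(sum(lg$grad^2))
    grad <- if (is.finite(gnorm) && gnorm > config$grad_clip) {
      lg$grad * (config$grad_clip / gnorm)
    } else lg$grad
    state$projection <- projection_step(state$projection, grad, config$lr)
  }

  state$voted <- voted
  state$iteration <- t_now
  state$log <- rbind(state$log,
    data.frame(iteration = t_now, added = nrow(added),
               mean_p = if (nrow(added)) mean(added$p) else NA_real_,
               loss = loss))
  state
}

# masks for one category across all groups; cached when the backend's
# output is a pure function of (group, inferred category), as the oracle's
# is — growing foreground prompts cannot change the majority category once
# every pseudo prompt carries the category it was admitted for
category_masks <- function(state, backend, groups, i) {
  key <- as.character(i)
  cache <- state$mask_cache
  if (static_masks(backend) && !is.null(cache[[key]])) return(cache[[key]])
  masks <- lapply(seq_along(groups), function(j) {
    segment(backend, groups[[j]], state$prompts[[i]], group = j)$mask
  })
  if (static_masks(backend)) cache[[key]] <- masks
  masks
}

static_masks <- function(backend) UseMethod("static_masks")
#' @export
static_masks.oracle_segmenter <- function(backend) TRUE
#' @export
static_masks.default <- function(backend) FALSE

#' Iterative pseudo-label generation from a handful of labelled pixels
#'
#' The main fitting function. Starting from a few seed labels per class,
#' the cube is decomposed into overlapping three-band groups, each group is
#' segmented per category with one-vs-rest point prompts, the per-group
#' masks are fused by spectral majority voting, and high-confidence,
#' low-uncertainty pixels of the voted map are admitted as pseudo-labels
#' and fed back as new foreground prompts — for a fixed number of
#' iterations, while a trainable projection of the prompt features is
#' optimised under the spatial-information-consistency loss.
#'
#' @param cube An [hsi_cube()].
#' @param seeds Seed labels from [sample_seed_labels()].
#' @param backend A `segmenter` backend, e.g. [oracle_segmenter()].
#' @param config An [ipg_config()].
#' @return An object of class `ipg`: the pseudo-label `ledger`
#'   (row, col, category, p, u, iteration), the final voted map, the final
#'   prompt sets and projection, the per-iteration log, and the inputs'
#'   echo.
#' @examples
#' sc <- generate_scene(scene_spec(H = 24, W = 24, C = 8, K = 3, noise_sd = 0, seed = 2))
#' seg <- oracle_segmenter(export_oracle(sc, flip_rate = 0))
#' seeds <- sample_seed_labels(sc$truth, per_class = 3, seed = 2)
#' fit <- ipg(sc$cube, seeds, seg, ipg_config(iterations = 5, seed = 2))
#' fit
#' @export
ipg <- function(cube, seeds, backend, config = ipg_config()) {
  stopifnot(inherits(config, "ipg_config"))
  groups <- lapply(decompose_bands(cube), normalize_group)
  emb <- embed_features(backend)
  state <- ipg_initialize(seeds, dim(emb)[3])
  for (t in seq_len(config$iterations)) {
    state <- ipg_iterate(state, backend, groups, config)
  }
  structure(list(ledger = state$ledger, voted = state$voted,
                 prompts = state$prompts, projection = state$projection,
                 log = state$log, seeds = seeds, config = config,
                 n_classes = state$K),
            class = "ipg")
}

#' @export
print.ipg <- function(x, ...) {
  cat(sprintf("Iterative pseudo-label generation: %d iterations, %d classes\n",
              x$config$iterations, x$n_classes))
  cat(sprintf("  seed labels: %d   pseudo-labels admitted: %d\n",
              nrow(x$seeds), nrow(x$ledger)))
  if (nrow(x$ledger)) {
    cat(sprintf("  mean confidence of admitted labels: %.4f (min %.4f)\n",
                mean(x$ledger$p), min(x$ledger$p)))
  }
  invisible(x)
}

#' @export
summary.ipg <- function(object, ...) {
  per_class <- if (nrow(object$ledger)) {
    as.data.frame(table(category = factor(object$ledger$category,
                                          levels = seq_len(object$n_classes))))
  } else {
    data.frame(category = factor(seq_len(object$n_classes)), Freq = 0L)
  }
  names(per_class)[2] <- "pseudo_labels"
  out <- list(ledger = object$ledger, per_class = per_class, log = object$log,
              thresholds = object$config$thresholds)
  class(out) <- "summary.ipg"
  out
}

#' @export
print.summary.ipg <- function(x, ...) {
  cat("Pseudo-labels per category:\n")
  print(x$per_class, row.names = FALSE)
  cat(sprintf("\nGate: p >= %.2f and u <= %.2f\n",
              x$thresholds$tau_h, x$thresholds$kappa_h))
  if (nrow(x$log)) {
    cat(sprintf("Final consistency loss: %.4f\n", utils::tail(x$log$loss, 1)))
  }
  invisible(x)
}

#' @export
plot.ipg <- function(x, ...) {
  lab <- unclass(x$voted$labels)
  graphics::image(t(lab[nrow(lab):1, , drop = FALSE]), axes = FALSE,
                  col = grDevices::hcl.colors(max(attr(x$voted$labels, "n_classes") + 1L, 2L),
                                              "Spectral"),
                  main = "Voted label map", ...)
  invisible(x)
}

#' Export the pseudo-label ledger as CSV
#'
#' @param fit An `ipg` fit.
#' @param path Output CSV path.
#' @export
write_ledger <- function(fit, path) {
  stopifnot(inherits(fit, "ipg"))
  utils::write.csv(fit$ledger, path, row.names = FALSE)
  invisible(path)
}
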