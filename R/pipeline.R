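#' Run the full pipeline on a synthetic scene
#'
#' Convenience wrapper tying the stages together: generate a scene, sample
#' seed labels, run the iterative pseudo-label generation, train the patch
#' classifier on seeds plus pseudo-labels (and, optionally, a paired
#' seeds-only baseline), and evaluate on the held-out pixels. Evaluation
#' pixels are all labelled pixels minus every pixel that entered training
#' in either arm (seeds and pseudo-labels), so the two arms are compared on
#' one common test set.
#'
#' @param spec A [scene_spec()].
#' @param oracle Oracle noise parameters passed to [export_oracle()].
#' @param per_class Seed labels per category.
#' @param config An [ipg_config()].
#' @param train A [train_config()].
#' @param baseline Also train and evaluate the seeds-only arm.
#' @param seed Global seed; fans out to per-stage seeds.
#' @return A list of class `ipg_pipeline` with the scene, seeds, `ipg`
#'   fit, both models and their [metric_report()]s.
#' @export
ipg_pipeline <- function(spec = scene_spec(), oracle = list(),
                         per_class = 5L, config = ipg_config(),
                         train = train_config(), baseline = TRUE, seed = 1L) {
  spec$seed <- as.integer(seed)
  config$seed <- as.integer(seed)
  train$seed <- as.integer(seed)
  scene <- generate_scene(spec)
  bundle <- do.call(export_oracle, c(list(scene), oracle))
  backend <- oracle_segmenter(bundle)
  seeds <- sample_seed_labels(scene$truth, per_class = per_class, seed = seed)
  fit <- ipg(scene$cube, seeds, backend, config)

  train_set <- build_training_set(seeds, fit)
  eval_px <- which(scene$truth > 0L, arr.ind = TRUE)
  used <- paste(train_set$row, train_set$col)
  eval_px <- eval_px[!(paste(eval_px[, 1], eval_px[, 2]) %in% used), , drop = FALSE]

  model <- hsi_cnn(extract_patches(scene$cube, train_set, size = 9L), train)
  pred <- predict(model, scene$cube)
  report <- metric_report(confusion_matrix(scene$truth, pred$labels, eval_px))

  base <- NULL
  if (baseline) {
    bmodel <- hsi_cnn(extract_patches(scene$cube, build_training_set(seeds), 9L), train)
    bpred <- predict(bmodel, scene$cube)
    base <- list(model = bmodel, pred = bpred,
                 report = metric_report(confusion_matrix(scene$truth, bpred$labels, eval_px)))
  }
  structure(list(scene = scene, seeds = seeds, fit = fit,
                 train_set = train_set, eval_pixels = eval_px,
                 model = model, pred = pred, report = report,
                 baseline = base, seed = as.integer(seed)),
            class = "ipg_pipeline")
}

#' @export
print.ipg_pipeline <- function(x, ...) {
  cat("IPG pipeline on synthetic scene\n")
  print(x$scene)
  cat(sprintf("  pseudo-labels: %d (precision vs truth: %.4f)\n",
              nrow(x$fit$ledger), pseudo_precision(x$fit, x$scene$truth)))
  cat(sprintf("  OA seeds+pseudo: %.2f%%   ", 100 * x$report$oa))
  if (!is.null(x$baseline)) cat(sprintf("OA seeds only: %.2f%%", 100 * x$baseline$report$oa))
  cat("\n")
  invisible(x)
}

#' Precision of a pseudo-label ledger against ground truth
#'
#' @param fit An `ipg` fit (or a ledger data frame).
#' @param truth Ground-truth [label_map()].
#' @return Fraction of admitted pseudo-labels whose category matches the
#'   ground truth; `NaN` for an empty ledger.
#' @export
pseudo_precision <- function(fit, truth) {
  led <- if (inherits(fit, "ipg")) fit$ledger else fit
  if (!nrow(led)) return(NaN)
  mean(truth[cbind(led$row, led$col)] == led$category)
}
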