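#' Confusion matrix over an evaluation pixel set
#'
#' Rows are true categories, columns predicted. Only the supplied
#' evaluation pixels are counted; they must all carry a nonzero
#' ground-truth label, and — to keep the evaluation honest — should exclude
#' every pixel that entered training (seeds and pseudo-labels).
#'
#' @param truth Ground-truth [label_map()].
#' @param pred Predicted [label_map()] (every eval pixel must be assigned).
#' @param eval_pixels Two-column matrix or data frame of (row, col); by
#'   default every labelled pixel of `truth`.
#' @return `K x K` integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(truth, pred, eval_pixels = NULL) {
  K <- attr(truth, "n_classes") %||% max(truth)
  if (is.null(eval_pixels)) eval_pixels <- which(truth > 0L, arr.ind = TRUE)
  eval_pixels <- as.matrix(as.data.frame(eval_pixels)[, 1:2])
  if (nrow(eval_pixels) == 0L) stop("empty evaluation pixel set")
  tt <- truth[eval_pixels]
  pp <- pred[eval_pixels]
  if (any(tt == 0L)) stop("evaluation pixels must be labelled in the ground truth")
  cm <- table(factor(tt, levels = seq_len(K)), factor(pp, levels = seq_len(K)))
  cm <- matrix(as.integer(cm), K, K,
               dimnames = list(true = seq_len(K), predicted = seq_len(K)))
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Accuracy metrics from a confusion matrix
#'
#' With `TP_i` the diagonal, `Total_i` the row sums and `FP_i` the column
#' sums minus the diagonal: overall accuracy `OA = sum TP_i / sum Total_i`;
#' average accuracy `AA = mean(TP_i / Total_i)`; the chance-agreement term
#' `Pe = sum(Total_i * (TP_i + FP_i)) / (sum Total_i)^2`; and Cohen's kappa
#' `(OA - Pe) / (1 - Pe)`. All are returned on the `[0, 1]` scale; reports
#' format them as percentages. When `Pe = 1` kappa is undefined and
#' returned as `NA`.
#'
#' @param cm A [confusion_matrix()] (any square nonnegative count matrix).
#' @return A scalar.
#' @export
overall_accuracy <- function(cm) {
  check_cm(cm)
  sum(diag(cm)) / sum(cm)
}

#' @rdname overall_accuracy
#' @export
average_accuracy <- function(cm) {
  check_cm(cm)
  tot <- rowSums(cm)
  if (any(tot == 0)) {
    stop("average accuracy is undefined with an empty class (zero row sum)")
  }
  mean(diag(cm) / tot)
}

#' @rdname overall_accuracy
#' @export
chance_agreement <- function(cm) {
  check_cm(cm)
  tot <- rowSums(cm)
  sum(tot * colSums(cm)) / sum(cm)^2
}

#' @rdname overall_accuracy
#' @export
kappa_coefficient <- function(cm) {
  pe <- chance_agreement(cm)
  if (pe >= 1) return(NA_real_)
  (overall_accuracy(cm) - pe) / (1 - pe)
}

check_cm <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  if (any(cm < 0) || any(cm != round(cm))) stop("confusion matrix must hold counts")
  if (sum(cm) == 0) stop("empty confusion matrix")
  invisible(TRUE)
}

#' Full metric report
#'
#' @param cm A [confusion_matrix()].
#' @return A list of class `metric_report`: per-class accuracy, OA, AA,
#'   Pe, and kappa.
#' @export
metric_report <- function(cm) {
  check_cm(cm)
  tot <- rowSums(cm)
  per_class <- ifelse(tot > 0, diag(cm) / tot, NA_real_)
  structure(list(per_class = per_class,
                 oa = overall_accuracy(cm),
                 aa = if (all(tot > 0)) average_accuracy(cm) else NA_real_,
                 pe = chance_agreement(cm),
                 kappa = kappa_coefficient(cm),
                 n = sum(cm)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Per-class accuracy (%):\n")
  tab <- data.frame(category = seq_along(x$per_class),
                    accuracy = sprintf("%.2f", 100 * x$per_class))
  print(tab, row.names = FALSE)
  cat(sprintf("OA (%%)    %.2f\n", 100 * x$oa))
  if (!is.na(x$aa)) cat(sprintf("AA (%%)    %.2f\n", 100 * x$aa))
  cat(sprintf("Kappa (%%) %s\n",
              if (is.na(x$kappa)) "undefined (Pe = 1)" else sprintf("%.2f", 100 * x$kappa)))
  invisible(x)
}

#' Write a metric report as JSON
#'
#' @param report A [metric_report()].
#' @param path Output path.
#' @export
write_metric_report <- function(report, path) {
  stopifnot(inherits(report, "metric_report"))
  jsonlite::write_json(
    list(per_class = as.numeric(report$per_class), oa = report$oa,
         aa = report$aa, pe = report$pe, kappa = report$kappa, n = report$n),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
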