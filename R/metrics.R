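# Evaluation metrics: confusion matrix, precision/recall/F1 (macro and
# support-weighted), and rank-based ROC-AUC (one-vs-rest macro for K > 2).

#' Confusion matrix from true and predicted codes
#'
#' @param truth,pred Integer vectors of 0-based class codes.
#' @param k Number of classes (default inferred).
#' @return `k x k` integer matrix, rows = truth, columns = prediction, so
#'   row sums equal class supports.
#' @export
confusion_matrix <- function(truth, pred, k = NULL) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  k <- k %||% (max(truth, pred) + 1L)
  cm <- matrix(0L, k, k)
  for (i in seq_along(truth))
    cm[truth[i] + 1L, pred[i] + 1L] <- cm[truth[i] + 1L, pred[i] + 1L] + 1L
  cm
}

# Rank-based binary AUC (equivalent to the normalized Mann-Whitney U).
binary_auc <- function(scores, positives) {
  n1 <- sum(positives); n0 <- sum(!positives)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)                      # average ranks for ties
  (sum(r[positives]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Compute a metrics report from predictions
#'
#' Precision/recall/F1 are reported macro-averaged (unweighted class mean)
#' and support-weighted. A class with zero predictions (undefined
#' precision) or zero support (undefined recall) scores 0 for the
#' undefined quantity, with a warning; this convention is what makes the
#' metrics of a degenerate all-one-class collapse reproducible (accuracy
#' 0.5 and macro F1 1/3 on a balanced binary set).
#'
#' ROC-AUC uses the rank statistic for K = 2 (scores = probability of the
#' positive class, i.e. code 1) and the unweighted one-vs-rest macro
#' average for K > 2.
#'
#' @param truth Integer vector of 0-based true codes.
#' @param pred Integer vector of 0-based predicted codes.
#' @param scores Optional `n x K` matrix of class scores/probabilities for
#'   ROC-AUC.
#' @param k Number of classes (default inferred).
#' @param vocabulary Optional class names for printing.
#' @return Object of class `metrics_report`: accuracy, macro/weighted
#'   precision, recall and F1, `roc_auc`, the confusion matrix, and
#'   per-class components.
#' @export
metrics_report <- function(truth, pred, scores = NULL, k = NULL,
                           vocabulary = NULL) {
  cm <- confusion_matrix(truth, pred, k)
  k <- nrow(cm)
  support <- rowSums(cm)
  predicted <- colSums(cm)
  tp <- diag(cm)
  prec <- ifelse(predicted > 0, tp / pmax(predicted, 1), 0)
  rec <- ifelse(support > 0, tp / pmax(support, 1), 0)
  if (any(predicted == 0))
    warning("class(es) with no predictions: precision scored as 0",
            call. = FALSE)
  if (any(support == 0))
    warning("class(es) with no support: recall scored as 0", call. = FALSE)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  wts <- support / sum(support)
  auc <- NA_real_
  if (!is.null(scores)) {
    scores <- rbind(scores)
    if (k == 2L) {
      auc <- binary_auc(scores[, 2], as.integer(truth) == 1L)
    } else {
      aucs <- vapply(seq_len(k) - 1L, function(c)
        binary_auc(scores[, c + 1L], as.integer(truth) == c), numeric(1))
      auc <- mean(aucs, na.rm = TRUE)
    }
  }
  if (!is.null(vocabulary)) {
    rownames(cm) <- colnames(cm) <- vocabulary
    names(prec) <- names(rec) <- names(f1) <- vocabulary
  }
  structure(list(accuracy = sum(tp) / sum(cm),
                 precision_macro = mean(prec),
                 recall_macro = mean(rec),
                 f1_macro = mean(f1),
                 precision_weighted = sum(prec * wts),
                 recall_weighted = sum(rec * wts),
                 f1_weighted = sum(f1 * wts),
                 roc_auc = auc,
                 confusion = cm,
                 per_class = list(precision = prec, recall = rec, f1 = f1,
                                  support = support)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat("Classification metrics\n")
  cat(sprintf("  accuracy        %.*f\n", digits, x$accuracy))
  cat(sprintf("  precision (macro/weighted) %.*f / %.*f\n", digits,
              x$precision_macro, digits, x$precision_weighted))
  cat(sprintf("  recall    (macro/weighted) %.*f / %.*f\n", digits,
              x$recall_macro, digits, x$recall_weighted))
  cat(sprintf("  F1        (macro/weighted) %.*f / %.*f\n", digits,
              x$f1_macro, digits, x$f1_weighted))
  if (!is.na(x$roc_auc))
    cat(sprintf("  ROC-AUC         %.*f\n", digits, x$roc_auc))
  cat("  confusion matrix (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

#' Evaluate a fitted model on a manifest
#'
#' Runs the model over every image in the manifest and computes the full
#' metrics report, including the one-vs-rest macro ROC-AUC from the
#' predicted probabilities.
#'
#' @param model A fitted [cytoxai()] model, or a path to a checkpoint
#'   written by it (read with `readRDS`).
#' @param manifest Manifest of evaluation images; labels must be covered by
#'   the model's vocabulary.
#' @param batch_size Forward-pass batch size (default 32).
#' @return A `metrics_report`.
#' @export
evaluate <- function(model, manifest, batch_size = 32L) {
  if (is.character(model)) model <- readRDS(model)
  stopifnot(inherits(model, "cytoxai"))
  manifest <- as_manifest(manifest)
  enc <- encode_labels(manifest$label, model$encoder)
  probs <- predict(model, manifest, type = "prob", batch_size = batch_size)
  pred <- max.col(probs, ties.method = "first") - 1L
  metrics_report(enc$codes, pred, scores = probs,
                 k = length(model$encoder$vocabulary),
                 vocabulary = model$encoder$vocabulary)
}
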