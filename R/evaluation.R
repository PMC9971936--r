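#' Confusion counts for binary AF/NSR classification
#'
#' AF is the positive class throughout the package.
#'
#' @param labels true labels.
#' @param predictions predicted labels.
#' @param positive positive-class label (default `"AF"`).
#' @return object of class `confusion_counts`: list with integer fields
#'   `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(labels, predictions, positive = "AF") {
  if (length(labels) != length(predictions)) {
    stop("labels and predictions differ in length")
  }
  truth <- as.character(labels) == positive
  pred <- as.character(predictions) == positive
  structure(list(tp = sum(truth & pred), fp = sum(!truth & pred),
                 fn = sum(truth & !pred), tn = sum(!truth & !pred)),
            class = "confusion_counts")
}

safe_ratio <- function(num, den) if (den > 0) num / den else NA_real_

#' Classification metrics from confusion counts
#'
#' Precision TP/(TP+FP), Recall TP/(TP+FN), Specificity TN/(TN+FP),
#' Accuracy (TP+TN)/total, and F1 as the harmonic mean
#' `2 * Precision * Recall / (Precision + Recall)`. A metric whose
#' denominator is zero is reported as `NA` (undefined, not zero) and
#' flagged in the `undefined` field.
#'
#' @param counts a [confusion()] result.
#' @return object of class `metrics_report`: list with `precision`,
#'   `recall`, `specificity`, `accuracy`, `f1`, `counts`, `undefined`.
#' @export
metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  precision <- safe_ratio(counts$tp, counts$tp + counts$fp)
  recall <- safe_ratio(counts$tp, counts$tp + counts$fn)
  specificity <- safe_ratio(counts$tn, counts$tn + counts$fp)
  total <- counts$tp + counts$fp + counts$fn + counts$tn
  accuracy <- safe_ratio(counts$tp + counts$tn, total)
  f1 <- f1_score(precision, recall)
  out <- list(precision = precision, recall = recall,
              specificity = specificity, accuracy = accuracy, f1 = f1,
              counts = counts)
  out$undefined <- names(which(vapply(
    out[c("precision", "recall", "specificity", "accuracy", "f1")],
    is.na, logical(1))))
  structure(out, class = "metrics_report")
}

#' F1 score from precision and recall
#'
#' The harmonic-mean identity `F1 = 2 P R / (P + R)`; usable directly on
#' printed precision/recall pairs.
#'
#' @param precision,recall values in `[0, 1]`.
#' @return F1 value, `NA` when `precision + recall == 0`.
#' @export
f1_score <- function(precision, recall) {
  if (is.na(precision) || is.na(recall)) return(NA_real_)
  if (precision + recall <= 0) return(NA_real_)
  2 * precision * recall / (precision + recall)
}

#' Accuracy implied by recall and specificity at a given prevalence
#'
#' `accuracy = prevalence * recall + (1 - prevalence) * specificity`; for
#' the balanced (prevalence 1/2) designs used here this is the plain mean
#' of recall and specificity.
#'
#' @param recall,specificity values in `[0, 1]`.
#' @param prevalence positive-class prevalence (default 0.5).
#' @return implied accuracy.
#' @export
balanced_accuracy <- function(recall, specificity, prevalence = 0.5) {
  prevalence * recall + (1 - prevalence) * specificity
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat(sprintf("F1 %.*f  Precision %.*f  Recall %.*f  Specificity %.*f  Accuracy %.*f\n",
              digits, x$f1, digits, x$precision, digits, x$recall,
              digits, x$specificity, digits, x$accuracy))
  if (length(x$undefined)) {
    cat("undefined (zero denominator):", paste(x$undefined, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Stratified record-disjoint k-fold assignment
#'
#' @param labels class labels, one per record.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids in `1..k`.
#' @export
make_folds <- function(labels, k, seed = 1L) {
  stopifnot(k >= 2)
  with_seed(seed, function() {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Cross-validated evaluation of a model factory
#'
#' Stratified, record-disjoint k-fold cross-validation: for each fold the
#' factory builds a fresh model, which is trained on the other folds and
#' evaluated on the held-out one.
#'
#' @param images list of per-record input arrays (see [stack_leads()]).
#' @param labels character labels, one per record.
#' @param model_factory function `(in_channels, seed)` returning an object
#'   with `$fit(x_list, labels)` and `$predict(x_list)` (see
#'   [parnet_factory()]).
#' @param k number of folds (default 5).
#' @param seed integer seed controlling fold assignment and per-fold model
#'   seeds.
#' @return list of per-fold `metrics_report`s, with the fold assignment in
#'   attribute `"folds"`.
#' @export
crossval <- function(images, labels, model_factory, k = 5L, seed = 1L) {
  fold <- make_folds(labels, k, seed)
  in_ch <- dim(if (inherits(images[[1]], "rp_image")) images[[1]]$pixels
               else images[[1]])[3]
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- which(fold != f)
    te <- which(fold == f)
    if (length(unique(labels[te])) < 2 || length(unique(labels[tr])) < 2) {
      stop("a fold contains a single class; use more records or fewer folds")
    }
    mdl <- model_factory(in_ch, seed = seed * 131L + f)
    mdl$fit(images[tr], labels[tr])
    pred <- mdl$predict(images[te])
    reports[[f]] <- metrics(confusion(labels[te], pred))
  }
  attr(reports, "folds") <- fold
  reports
}
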