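#' Four-class confusion matrix
#'
#' Rows are the predicted class, columns the ground-truth class, both in the
#' canonical order AF, Normal, Noisy, Other.
#'
#' @param truth Character vector of true labels.
#' @param predicted Character vector of predicted labels (same length).
#' @return 4x4 integer matrix of class `confusion4`.
#' @export
#' @examples
#' confusion4(c("AF", "Normal"), c("Other", "Normal"))
confusion4 <- function(truth, predicted) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length", call. = FALSE)
  }
  check_labels(truth, "truth label")
  check_labels(predicted, "predicted label")
  cm <- table(factor(predicted, levels = af_classes()),
              factor(truth, levels = af_classes()))
  m <- matrix(as.integer(cm), 4, 4,
              dimnames = list(predicted = af_classes(),
                              truth = af_classes()))
  class(m) <- c("confusion4", class(m))
  m
}

#' Collapse a 4x4 confusion matrix to one-vs-rest 2x2 counts
#'
#' For a chosen target class: true positives are the diagonal cell, false
#' positives the rest of the target's prediction row, false negatives the
#' rest of the target's truth column, true negatives the remainder. Totals
#' are conserved.
#'
#' @param cm A [confusion4()] matrix.
#' @param target One of [af_classes()].
#' @return A list of class `binary_confusion` with fields `tp`, `fp`, `fn`,
#'   `tn` and the `target` class.
#' @export
collapse_confusion <- function(cm, target) {
  check_labels(target, "target class")
  stopifnot(all(dim(cm) == c(4, 4)))
  t_i <- match(target, af_classes())
  tp <- cm[t_i, t_i]
  fp <- sum(cm[t_i, -t_i])
  fn <- sum(cm[-t_i, t_i])
  tn <- sum(cm[-t_i, -t_i])
  structure(list(tp = as.numeric(tp), fp = as.numeric(fp),
                 fn = as.numeric(fn), tn = as.numeric(tn), target = target),
            class = "binary_confusion")
}

# internal: ratio in percent with the documented zero-denominator convention
pct_ratio <- function(num, den, what) {
  if (den <= 0) {
    warning(sprintf("%s undefined (zero denominator); reported as 0", what),
            call. = FALSE)
    return(0)
  }
  100 * num / den
}

#' Precision of a one-vs-rest confusion
#'
#' `tp / (tp + fp)`, in percent. A zero denominator is reported as 0 with a
#' warning.
#'
#' @param bc A [collapse_confusion()] result.
#' @return Percent in `[0, 100]`.
#' @export
precision_pct <- function(bc) pct_ratio(bc$tp, bc$tp + bc$fp, "precision")

#' Recall of a one-vs-rest confusion
#'
#' `tp / (tp + fn)`, in percent; zero denominator reported as 0 with a
#' warning.
#'
#' @param bc A [collapse_confusion()] result.
#' @return Percent in `[0, 100]`.
#' @export
recall_pct <- function(bc) pct_ratio(bc$tp, bc$tp + bc$fn, "recall")

#' Accuracy of a one-vs-rest confusion
#'
#' `(tp + tn) / total`, in percent.
#'
#' @param bc A [collapse_confusion()] result.
#' @return Percent in `[0, 100]`.
#' @export
accuracy_pct <- function(bc) {
  pct_ratio(bc$tp + bc$tn, bc$tp + bc$fp + bc$fn + bc$tn, "accuracy")
}

#' F1 score from precision and recall (percent)
#'
#' Harmonic mean `2 P R / (P + R)`; when both are zero the score is 0 by
#' convention.
#'
#' @param precision,recall Percent values in `[0, 100]`.
#' @return Percent in `[0, 100]`.
#' @export
#' @examples
#' f1_pct(100, 50)
f1_pct <- function(precision, recall) {
  if (precision < 0 || recall < 0) stop("negative precision/recall",
                                        call. = FALSE)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Full metrics report from a four-class confusion matrix
#'
#' Per-class precision, recall and F1 via the one-vs-rest collapse, overall
#' accuracy (trace over total), the four-class average F1 (the headline
#' score) and the three-class average over AF, Normal and Other.
#'
#' @param cm A [confusion4()] matrix.
#' @return An object of class `metrics_report`: list with `per_class` (data
#'   frame of precision/recall/F1 per class), `accuracy`, `average_f1`,
#'   `average_f1_3class`. All values in percent.
#' @export
metrics_report <- function(cm) {
  per <- lapply(af_classes(), function(cl) {
    bc <- collapse_confusion(cm, cl)
    p <- precision_pct(bc)
    r <- recall_pct(bc)
    data.frame(class = cl, precision = p, recall = r, f1 = f1_pct(p, r),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  structure(list(per_class = per,
                 accuracy = 100 * sum(diag(cm)) / max(1, sum(cm)),
                 average_f1 = mean(per$f1),
                 average_f1_3class = mean(per$f1[per$class != "Noisy"])),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  print(x$per_class, row.names = FALSE, digits = 4)
  cat(sprintf("  accuracy %.1f%%, average F1 %.1f%% (3-class %.1f%%)\n",
              x$accuracy, x$average_f1, x$average_f1_3class))
  invisible(x)
}

#' Average F1 over the four rhythm classes
#'
#' Arithmetic mean of the four per-class F1 scores (percent).
#'
#' @param f1_values Numeric vector of four per-class F1 values, in the order
#'   AF, Normal, Noisy, Other (names are ignored).
#' @return Percent value.
#' @export
#' @examples
#' average_f1(c(79.1, 90.7, 65.3, 76.0))
average_f1 <- function(f1_values) {
  stopifnot(length(f1_values) == 4)
  mean(f1_values)
}

#' Aggregate per-fold metrics reports
#'
#' Per-class and overall metrics are averaged over folds; the spread is the
#' standard deviation of the fold-level average F1 (population by default,
#' i.e. divisor `n`; set `sd_type = "sample"` for divisor `n - 1`).
#'
#' @param per_fold List of [metrics_report()] objects, one per fold.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return A `cv_report`: list with `per_class` (fold-mean data frame),
#'   `accuracy`, `average_f1`, `average_f1_3class`, `sigma`, `n_folds`, and
#'   `fold_average_f1` (the per-fold values).
#' @export
cv_report <- function(per_fold, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  stopifnot(length(per_fold) >= 1,
            all(vapply(per_fold, inherits, logical(1), "metrics_report")))
  per <- Reduce(function(a, b) {
    a[, -1] <- a[, -1] + b[, -1]
    a
  }, lapply(per_fold, function(r) r$per_class))
  per[, -1] <- per[, -1] / length(per_fold)
  favg <- vapply(per_fold, function(r) r$average_f1, numeric(1))
  sigma <- if (length(favg) == 1) 0 else if (sd_type == "population") {
    sqrt(mean((favg - mean(favg))^2))
  } else {
    stats::sd(favg)
  }
  structure(list(per_class = per,
                 accuracy = mean(vapply(per_fold, function(r) r$accuracy,
                                        numeric(1))),
                 average_f1 = mean(favg),
                 average_f1_3class = mean(vapply(per_fold, function(r)
                   r$average_f1_3class, numeric(1))),
                 sigma = sigma, n_folds = length(per_fold),
                 fold_average_f1 = favg),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d folds: average F1 %.1f%% (sigma %.1f)\n",
              x$n_folds, x$average_f1, x$sigma))
  print(x$per_class, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Train and evaluate one architecture by stratified K-fold CV
#'
#' For each fold, trains a freshly built network on the remaining folds and
#' evaluates the held-out fold with [metrics_report()]. Stratification is at
#' segment level by default, matching how the pre-processed Challenge
#' segments were cross-validated; `grouped = TRUE` instead assigns whole
#' source recordings to folds so sibling segments never straddle the
#' train/test boundary.
#'
#' @param dataset A `segment_dataset`.
#' @param spec An [architecture_spec()].
#' @param config A [train_config()].
#' @param k Number of folds (default 5).
#' @param seed Seed for fold assignment and per-fold model initialization.
#' @param grouped Use record-grouped fold assignment (default `FALSE`).
#' @return A `cv_report` with an extra `folds` attribute carrying the
#'   per-fold confusion matrices.
#' @export
cross_validate <- function(dataset, spec, config = train_config(), k = 5L,
                           seed = 1L, grouped = FALSE) {
  labels <- as.character(dataset$info$label)
  if (grouped) {
    ids <- unique(dataset$info$source_id)
    rec_lab <- labels[match(ids, dataset$info$source_id)]
    fs_rec <- stratified_kfold(rec_lab, k, seed)
    assignments <- fs_rec$assignments[match(dataset$info$source_id, ids)]
  } else {
    assignments <- stratified_kfold(labels, k, seed)$assignments
  }
  reports <- list()
  cms <- list()
  for (fold in seq_len(k)) {
    test_idx <- which(assignments == fold)
    train_idx <- which(assignments != fold)
    model <- build_network(spec, seed = seed + fold)
    cfg <- config
    cfg$seed <- config$seed + fold
    if (cfg$epochs > 0) {
      model <- fit(model, subset_segments(dataset, train_idx), cfg)
    }
    pr <- predict(model, subset_segments(dataset, test_idx))
    cm <- confusion4(labels[test_idx], pr$labels)
    cms[[fold]] <- cm
    reports[[fold]] <- metrics_report(cm)
  }
  rep <- cv_report(reports)
  attr(rep, "folds") <- cms
  rep
}
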