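#' Stratified train/test split
#'
#' Splits records into disjoint, exhaustive train and test index sets,
#' stratified by the pneumothorax label: each class contributes
#' `round(ratio * n_class)` records to the training set (clamped so both
#' splits keep at least one record per class). Stratification matters
#' here because at sub-percent prevalence an unstratified 80/20 split is
#' frequently positive-free in the test set.
#'
#' @param records Record tibble with a `label_pneumothorax` column, or a
#'   logical label vector.
#' @param ratio Training fraction in (0, 1); default 0.8.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(records, ratio = 0.8, seed = 1L) {
  labels <- if (is.data.frame(records)) records$label_pneumothorax else records
  labels <- as.logical(labels)
  if (!is.numeric(ratio) || ratio <= 0 || ratio >= 1) {
    stop_invalid("ratio must lie strictly between 0 and 1 (both splits non-empty)")
  }
  tab <- table(labels)
  if (length(tab) < 2L || any(tab < 2L)) {
    stop_invalid("each class needs at least 2 records to stratify")
  }
  withr::with_seed(seed, {
    train <- integer(0)
    for (cls in c(FALSE, TRUE)) {
      idx <- which(labels == cls)
      n_tr <- round(ratio * length(idx))
      n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
      train <- c(train, sample(idx, n_tr))
    }
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Confusion matrix from truth and prediction
#'
#' @param truth,predicted Logical vectors of equal length.
#' @return List of class `confusion_matrix` with fields `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
confusion_matrix <- function(truth, predicted) {
  truth <- as.logical(truth); predicted <- as.logical(predicted)
  stopifnot(length(truth) == length(predicted))
  structure(list(
    tp = sum(truth & predicted),
    fp = sum(!truth & predicted),
    tn = sum(!truth & !predicted),
    fn = sum(truth & !predicted)
  ), class = "confusion_matrix")
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy (tp+tn)/total, sensitivity tp/(tp+fn), specificity
#' tn/(tn+fp), F1 2tp/(2tp+fp+fn). An empty class denominator raises an
#' explicit undefined-metric error rather than silently returning 0.
#'
#' @param cm A [confusion_matrix()].
#' @return Named list `accuracy`, `sensitivity`, `specificity`, `f1`.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$tp + cm$fn == 0L) {
    stop_invalid("undefined metric: no positive records (tp + fn = 0)")
  }
  if (cm$tn + cm$fp == 0L) {
    stop_invalid("undefined metric: no negative records (tn + fp = 0)")
  }
  total <- cm$tp + cm$fp + cm$tn + cm$fn
  list(accuracy = (cm$tp + cm$tn) / total,
       sensitivity = cm$tp / (cm$tp + cm$fn),
       specificity = cm$tn / (cm$tn + cm$fp),
       f1 = 2 * cm$tp / (2 * cm$tp + cm$fp + cm$fn))
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over every distinct score (predicting
#' positive at `score >= threshold`), anchors the curve at (0,0) and
#' (1,1), and integrates by the trapezoidal rule. The resulting AUC
#' equals the Mann-Whitney statistic
#' \eqn{P(s^+ > s^-) + \tfrac{1}{2} P(s^+ = s^-)}.
#'
#' @param labels Logical vector (truth).
#' @param scores Numeric scores (e.g. forest vote fractions).
#' @return List with `points` (tibble `threshold`, `fpr`, `tpr`,
#'   monotone, starting at (0,0) and ending at (1,1)) and `auc`.
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.logical(labels)
  stopifnot(length(labels) == length(scores))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop_invalid("ROC requires both classes")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !labels) / n_neg, numeric(1))
  pts <- tibble::tibble(threshold = c(Inf, thr, -Inf),
                        fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  pts <- pts[!duplicated(pts[c("fpr", "tpr")]), ]
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Held-out evaluation report
#'
#' Bundles the confusion matrix at the vote threshold, the four headline
#' metrics, and the ROC/AUC of the continuous scores.
#'
#' @param truth Logical vector.
#' @param scores Numeric scores.
#' @param threshold Classification threshold (ties positive).
#' @return List of class `evaluation_report` with `confusion`, `accuracy`,
#'   `sensitivity`, `specificity`, `f1`, `auc`, `roc_points`.
#' @export
evaluation_report <- function(truth, scores, threshold = 0.5) {
  cm <- confusion_matrix(truth, scores >= threshold)
  metrics <- compute_metrics(cm)
  roc <- roc_auc(truth, scores)
  structure(c(list(confusion = cm), metrics,
              list(auc = roc$auc, roc_points = roc$points)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cm <- x$confusion
  cat(sprintf("<evaluation_report> tp=%d fp=%d tn=%d fn=%d\n",
              cm$tp, cm$fp, cm$tn, cm$fn))
  cat(sprintf("  accuracy %.3f | sensitivity %.3f | specificity %.3f | f1 %.3f | auc %.4f\n",
              x$accuracy, x$sensitivity, x$specificity, x$f1, x$auc))
  invisible(x)
}
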