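#' Random-forest configuration
#'
#' Hyperparameters of the report classifier: an ensemble of `n_trees`
#' decision trees grown on bootstrap resamples, `mtry` candidate
#' predictors per split, splits chosen to minimize child-weighted Gini
#' impurity. The defaults (250 trees, mtry = 2) are the settings the
#' pipeline was tuned to; mtry = 2 is deliberately small relative to a
#' bi-gram vocabulary and is exposed here as configuration.
#'
#' @param n_trees Number of trees (default 250).
#' @param mtry Candidate predictors per split (default 2).
#' @param vote_threshold Fraction of positive tree votes at or above
#'   which a record is classified positive (default 0.5; ties go
#'   positive).
#' @param seed Integer seed; training is deterministic for a fixed seed.
#' @return List of class `forest_config`.
#' @export
forest_config <- function(n_trees = 250L, mtry = 2L, vote_threshold = 0.5,
                          seed = 1L) {
  if (!is.numeric(n_trees) || n_trees < 1) stop_invalid("n_trees must be >= 1")
  if (!is.numeric(mtry) || mtry < 1) stop_invalid("mtry must be >= 1")
  if (!is_prop(vote_threshold)) stop_invalid("vote_threshold must lie in [0,1]")
  structure(list(n_trees = as.integer(n_trees), mtry = as.integer(mtry),
                 split_criterion = "gini", vote_threshold = vote_threshold,
                 seed = as.integer(seed)),
            class = "forest_config")
}

#' Train the Gini random forest
#'
#' Thin wrapper over [ranger::ranger()] that pins the study
#' hyperparameters: `num.trees = n_trees`, `mtry`, `splitrule = "gini"`,
#' single-threaded and seeded for bit reproducibility. Labels are logical
#' (`TRUE` = pneumothorax).
#'
#' @param features Numeric matrix with column names (the vocabulary).
#' @param labels Logical vector.
#' @param config A [forest_config()].
#' @return Object of class `pneumo_forest`.
#' @export
train_forest <- function(features, labels, config = forest_config()) {
  features <- as.matrix(features)
  labels <- as.logical(labels)
  if (nrow(features) == 0L || ncol(features) == 0L) {
    stop_invalid("features must be a non-empty matrix")
  }
  if (length(unique(labels)) < 2L) {
    stop_invalid("training requires both classes")
  }
  if (config$mtry > ncol(features)) {
    stop_invalid("mtry (%d) exceeds the number of features (%d)",
                 config$mtry, ncol(features))
  }
  if (is.null(colnames(features))) {
    colnames(features) <- sprintf("f%05d", seq_len(ncol(features)))
  }
  y <- factor(ifelse(labels, "pos", "neg"), levels = c("neg", "pos"))
  fit <- ranger::ranger(x = features, y = y,
                        num.trees = config$n_trees,
                        mtry = config$mtry,
                        splitrule = "gini",
                        seed = config$seed,
                        num.threads = 1L)
  structure(list(forest = fit, config = config,
                 vocabulary = colnames(features)),
            class = "pneumo_forest")
}

#' Predict with a trained forest
#'
#' The continuous score of a record is its vote fraction: the share of
#' trees voting "pneumothorax". The hard label is `score >=
#' vote_threshold` (ties classified positive). Feature columns must match
#' the training vocabulary.
#'
#' @param object A `pneumo_forest`.
#' @param features Numeric matrix over the training vocabulary.
#' @param ... Unused.
#' @return List with `labels` (logical) and `scores` (vote fractions in
#'   \[0, 1\]).
#' @export
predict.pneumo_forest <- function(object, features, ...) {
  features <- as.matrix(features)
  if (ncol(features) != length(object$vocabulary)) {
    stop_invalid("feature dimension mismatch: model has %d features, input %d",
                 length(object$vocabulary), ncol(features))
  }
  if (!is.null(colnames(features)) &&
      !identical(colnames(features), object$vocabulary)) {
    stop_invalid("feature columns do not match the training vocabulary")
  }
  colnames(features) <- object$vocabulary
  pr <- predict(object$forest, data = features, predict.all = TRUE,
                num.threads = 1L)$predictions
  # per-tree predictions are class values; map to the "pos" level
  lv <- object$forest$forest$levels
  cv <- object$forest$forest$class.values
  pos_value <- cv[which(lv == "pos")]
  scores <- rowMeans(pr == pos_value)
  list(labels = scores >= object$config$vote_threshold, scores = scores)
}
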