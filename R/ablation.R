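#' Define an ablation grid
#'
#' Builds the cell table for [run_ablation()]: the full cross of
#' stopword handling, n-gram order, SMOTE on/off, and forest sizes. The
#' defaults enumerate the configurations studied when tuning the
#' pipeline (custom stopwords on/off; bi-grams vs tri-grams; class
#' balancing on/off; 100–300 trees).
#'
#' @param stopwords Logical values to test.
#' @param ngram_order N-gram orders to test (2 and/or 3).
#' @param smote Logical values to test.
#' @param n_trees Tree counts to test.
#' @return Tibble with one row per grid cell.
#' @export
ablation_grid <- function(stopwords = c(TRUE, FALSE),
                          ngram_order = c(2L, 3L),
                          smote = c(TRUE, FALSE),
                          n_trees = c(100L, 150L, 200L, 250L, 300L)) {
  tibble::as_tibble(expand.grid(stopwords = stopwords,
                                ngram_order = as.integer(ngram_order),
                                smote = smote,
                                n_trees = as.integer(n_trees),
                                KEEP.OUT.ATTRS = FALSE))
}

#' Run the ablation study
#'
#' Executes one full classification run per grid cell on a fixed corpus.
#' All cells share the same split seed (derived from the base config),
#' so their held-out sets are identical whenever the label vector is —
#' cells are directly comparable. A failing cell is recorded in its
#' `error` column and the grid completes.
#'
#' @param records Post-exclusion corpus tibble (texts filled).
#' @param grid Tibble from [ablation_grid()] (or any subset of its
#'   columns' combinations).
#' @param config Base `run_config`; each cell overrides
#'   `features$use_stopwords`, `features$ngram_order`, `smote$enabled`
#'   and `forest$n_trees`.
#' @return The grid with result columns `accuracy`, `sensitivity`,
#'   `specificity`, `f1`, `auc`, `fingerprint`, `error`.
#' @export
run_ablation <- function(records, grid = ablation_grid(),
                         config = default_config()) {
  if (nrow(grid) == 0L) stop_invalid("ablation grid is empty")
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- config
    cfg$features$use_stopwords <- grid$stopwords[i]
    cfg$features$ngram_order <- grid$ngram_order[i]
    cfg$smote$enabled <- grid$smote[i]
    cfg$forest$n_trees <- grid$n_trees[i]
    out <- tryCatch({
      r <- run_classifier(records, cfg)
      tibble::tibble(accuracy = r$report$accuracy,
                     sensitivity = r$report$sensitivity,
                     specificity = r$report$specificity,
                     f1 = r$report$f1,
                     auc = r$report$auc,
                     fingerprint = r$fingerprint,
                     error = NA_character_)
    }, error = function(e) {
      tibble::tibble(accuracy = NA_real_, sensitivity = NA_real_,
                     specificity = NA_real_, f1 = NA_real_, auc = NA_real_,
                     fingerprint = NA_character_,
                     error = conditionMessage(e))
    })
    out
  })
  cbind(grid, do.call(rbind, res))
}

#' Export ablation results as CSV
#'
#' Flat one-row-per-cell export of [run_ablation()] output.
#'
#' @param results Tibble returned by [run_ablation()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ablation_csv <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}
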