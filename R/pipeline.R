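#' Default pipeline configuration
#'
#' A nested run configuration covering every stage: cohort generation,
#' lexicon, text features, SMOTE, forest, split and statistics. Every
#' stage seed is derived from the single global `seed` by fixed,
#' documented offsets (cohort +101, lexicon +211, split +307, SMOTE
#' +401, forest +503), so ablation cells can share the split while
#' differing only where intended. All values can be overridden via
#' [read_run_config()] YAML or by modifying the returned list.
#'
#' @param seed Global integer seed.
#' @param n_records Cohort size.
#' @param language Lexicon language, `"de"` (default) or `"en"`.
#' @return Nested list of class `run_config`.
#' @export
default_config <- function(seed = 1L, n_records = 2000L, language = "de") {
  structure(list(
    seed = as.integer(seed),
    language = language,
    cohort = list(
      n_records = as.integer(n_records),
      insertion_fraction = 16380 / 17175,
      male_fraction = 0.545,
      age_distribution = list(mean = 84.259, sd = 41.288, min = 18, max = 101),
      outcome_model = list(intercept = -4.396298, beta_age = -0.011809,
                           beta_gender = 0.200964),
      size_distribution = list(mean = 40, sd = 25, min = 2, max = 140),
      hours_range = c(0, 24)),
    lexicon = list(
      misspelling_rate = 0,
      negation_distractor_rate = 0.3,
      contraindication_rate = 0.05,
      abbreviation_rate = 0.3,
      include_size_sentence = TRUE),
    features = list(ngram_order = 2L, prune_fraction = 0.01,
                    prune_mode = "doc_freq", use_stopwords = TRUE),
    smote = list(enabled = TRUE, k_neighbors = 5L, target_ratio = 1),
    forest = list(n_trees = 250L, mtry = 2L, vote_threshold = 0.5),
    split = list(ratio = 0.8),
    stats = list(continuity_correction = TRUE)
  ), class = "run_config")
}

#' Versioned benchmark configuration
#'
#' The packaged benchmark corpus on which the classifier's headline
#' metrics are reported: 8,000 already-screened reports (all within the
#' 12-hour window), ~8% pneumothorax prevalence (outcome-model intercept
#' calibrated by [calibrate_outcome_intercept()], age and gender effects
#' unchanged), misspelling rate 0.10, negation-distractor rate 0.30,
#' seed 42. The difficulty of this corpus is fixed here; changing it
#' changes the benchmark.
#'
#' @param seed Global seed (default 42, the versioned benchmark seed).
#' @return A `run_config`.
#' @export
benchmark_config <- function(seed = 42L) {
  cfg <- default_config(seed = seed, n_records = 8000L, language = "de")
  cfg$cohort$hours_range <- c(0, 12)
  base <- do.call(cohort_params, c(cfg$cohort, list(seed = 0L)))
  cfg$cohort$outcome_model$intercept <-
    calibrate_outcome_intercept(base, target_prevalence = 0.08)
  cfg$lexicon$misspelling_rate <- 0.10
  cfg$lexicon$negation_distractor_rate <- 0.30
  cfg
}

#' Read / write a run configuration as YAML
#'
#' YAML blocks mirror the [default_config()] structure (`cohort:`,
#' `lexicon:`, `features:`, `smote:`, `forest:`, `split:`, `stats:`,
#' `seed:`); missing entries fall back to the defaults, so a config file
#' only needs the overrides. Configs round-trip through serialization.
#'
#' @param path YAML file path.
#' @param config A `run_config` (for writing).
#' @return A `run_config` (`read_run_config`); `path` invisibly
#'   (`write_run_config`).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- merge_config(default_config(), raw)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Fingerprint of a run configuration
#'
#' MD5 of the canonical serialization of all configs and seeds; two runs
#' with the same fingerprint are byte-reproducible.
#'
#' @param config A `run_config` (or any list).
#' @return Hex string.
#' @export
config_fingerprint <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(unclass(config), tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}

stage_seed <- function(config, stage) {
  config$seed + c(cohort = 101L, lexicon = 211L, split = 307L,
                  smote = 401L, forest = 503L)[[stage]]
}

build_lexicon <- function(config) {
  lx <- config$lexicon
  lexicon_config(language = config$language,
                 misspelling_rate = lx$misspelling_rate,
                 negation_distractor_rate = lx$negation_distractor_rate,
                 contraindication_rate = lx$contraindication_rate,
                 abbreviation_rate = lx$abbreviation_rate,
                 include_size_sentence = lx$include_size_sentence,
                 seed = stage_seed(config, "lexicon"))
}

record_tokens <- function(records, stopwords, abbreviation_map = list()) {
  lapply(seq_len(nrow(records)), function(i) {
    toks <- c("reporttext", normalize_text(records$report_text[i], stopwords),
              "requesttext", normalize_text(records$request_text[i], stopwords))
    canonicalize_tokens(toks, abbreviation_map)
  })
}

#' Train and evaluate the classifier on a corpus
#'
#' The classification core shared by [run_pipeline()] and
#' [run_ablation()]: normalizes report and request texts (concatenated
#' with sentinel prefix tokens `reporttext` / `requesttext`), splits
#' stratified 80/20, fits the n-gram vocabulary and pruning on the
#' training split only, projects the test split onto it, optionally
#' SMOTE-balances the training rows, trains the Gini forest and
#' evaluates on the held-out vote fractions.
#'
#' @param records Corpus tibble with texts filled (post-exclusion).
#' @param config A `run_config`.
#' @return List with `report` ([evaluation_report()]), `model`, `split`,
#'   `vocabulary`, `fingerprint`.
#' @export
run_classifier <- function(records, config) {
  sw <- if (isTRUE(config$features$use_stopwords)) {
    default_stopwords(config$language)
  } else character()
  # the curated abbreviation inventory feeds preprocessing, mirroring the
  # phrase-detection stage of the workflow (labels are never consulted)
  abbr <- build_lexicon(config)$abbreviation_map
  tokens <- record_tokens(records, sw, abbr)
  labels <- records$label_pneumothorax
  split <- split_train_test(labels, ratio = config$split$ratio,
                            seed = stage_seed(config, "split"))
  dtm_train <- build_dtm(tokens[split$train], n = config$features$ngram_order)
  dtm_train <- prune_features(dtm_train,
                              fraction = config$features$prune_fraction,
                              mode = config$features$prune_mode)
  dtm_test <- project_dtm(tokens[split$test], dtm_train$vocabulary,
                          n = config$features$ngram_order)
  x_train <- as.matrix(dtm_train$counts)
  y_train <- labels[split$train]
  if (isTRUE(config$smote$enabled)) {
    bal <- balance_dataset(x_train, y_train,
                           smote_config(k_neighbors = config$smote$k_neighbors,
                                        target_ratio = config$smote$target_ratio,
                                        seed = stage_seed(config, "smote")))
    x_train <- bal$features
    y_train <- bal$labels
  }
  fc <- forest_config(n_trees = config$forest$n_trees,
                      mtry = config$forest$mtry,
                      vote_threshold = config$forest$vote_threshold,
                      seed = stage_seed(config, "forest"))
  model <- train_forest(x_train, y_train, fc)
  pred <- predict(model, as.matrix(dtm_test$counts))
  report <- evaluation_report(labels[split$test], pred$scores,
                              threshold = config$forest$vote_threshold)
  list(report = report, model = model, split = split,
       vocabulary = dtm_train$vocabulary,
       fingerprint = config_fingerprint(config))
}

#' Run the full pipeline
#'
#' generate -> render texts -> apply exclusions -> classify -> evaluate
#' -> epidemiological statistics, all seeded from the global config
#' seed. Optionally writes artifacts (corpus JSONL, model RDS, metrics
#' JSON, stats JSON, run log) to `out_dir`.
#'
#' @param config A `run_config` (see [default_config()],
#'   [benchmark_config()]).
#' @param out_dir Optional output directory.
#' @return List with `report` (classifier evaluation), `stats`
#'   (incidence summary, chi-square, logistic and size-model fits),
#'   `corpus` (the post-exclusion records), `excluded` (count),
#'   `model`, `fingerprint`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  params <- do.call(cohort_params,
                    c(config$cohort, list(seed = stage_seed(config, "cohort"))))
  cohort <- generate_cohort(params)
  lexicon <- build_lexicon(config)
  corpus <- generate_corpus(cohort, lexicon)
  excl <- apply_exclusions(corpus)
  kept <- corpus[excl$included, ]

  cls <- run_classifier(kept, config)

  inc <- incidence_summary(kept)
  chi <- tryCatch(
    chi_square_2x2(inc$table, config$stats$continuity_correction),
    error = function(e) list(error = conditionMessage(e)))
  logit <- tryCatch(
    fit_logistic(kept$age_years, kept$gender == "male",
                 kept$label_pneumothorax),
    error = function(e) list(error = conditionMessage(e)))
  sizes <- kept[kept$label_pneumothorax & !is.na(kept$pneumothorax_size_mm), ]
  linfit <- tryCatch(
    fit_linear_size(sizes$pneumothorax_size_mm, sizes$procedure == "removal"),
    error = function(e) list(error = conditionMessage(e)))
  stats_out <- list(incidence = inc, chi_square = chi, logistic = logit,
                    size_model = linfit)

  result <- list(report = cls$report, stats = stats_out, corpus = kept,
                 excluded = sum(!excl$included), model = cls$model,
                 fingerprint = cls$fingerprint)
  if (!is.null(out_dir)) write_run_artifacts(result, config, out_dir)
  result
}

metrics_json <- function(report, fingerprint) {
  jsonlite::toJSON(list(
    accuracy = report$accuracy, sensitivity = report$sensitivity,
    specificity = report$specificity, f1 = report$f1, auc = report$auc,
    confusion = unclass(report$confusion),
    config_fingerprint = fingerprint), auto_unbox = TRUE, digits = NA)
}

write_run_artifacts <- function(result, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_corpus(result$corpus, file.path(out_dir, "corpus.jsonl"))
  saveRDS(result$model, file.path(out_dir, "model.rds"))
  writeLines(as.character(metrics_json(result$report, result$fingerprint)),
             file.path(out_dir, "metrics.json"))
  st <- result$stats
  stats_list <- list(
    incidence = list(table = st$incidence$table,
                     summary = st$incidence$summary,
                     shares = as.list(st$incidence$shares)),
    chi_square = st$chi_square[c("statistic", "p_value")],
    logistic = if (is.null(st$logistic$error)) {
      list(coefficients = as.list(st$logistic$coefficients),
           standard_errors = as.list(st$logistic$standard_errors),
           p_values = as.list(st$logistic$p_values),
           null_deviance = st$logistic$null_deviance,
           residual_deviance = st$logistic$residual_deviance,
           aic = st$logistic$aic)
    } else st$logistic,
    size_model = if (is.null(st$size_model$error)) {
      st$size_model[c("intercept", "slope", "slope_p_value")]
    } else st$size_model)
  writeLines(as.character(jsonlite::toJSON(stats_list, auto_unbox = TRUE,
                                           digits = NA)),
             file.path(out_dir, "stats.json"))
  writeLines(c(sprintf("pneumotext run %s", format(Sys.time())),
               sprintf("config fingerprint: %s", result$fingerprint),
               sprintf("records kept: %d (excluded %d)",
                       nrow(result$corpus), result$excluded)),
             file.path(out_dir, "run.log"))
  write_run_config(config, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}
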