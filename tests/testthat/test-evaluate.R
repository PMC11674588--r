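test_that("stratified splitting preserves class shares and is seeded", {
  labels <- c(rep(TRUE, 10), rep(FALSE, 90))
  sp <- split_train_test(labels, ratio = 0.8, seed = 3)
  expect_equal(length(sp$train), 80)
  expect_equal(sum(labels[sp$train]), 8)
  expect_equal(sort(c(sp$train, sp$test)), 1:100)  # disjoint, exhaustive
  expect_identical(sp, split_train_test(labels, ratio = 0.8, seed = 3))
  expect_false(identical(sp, split_train_test(labels, ratio = 0.8, seed = 4)))

  expect_error(split_train_test(labels, ratio = 1.0), "strictly between")
  expect_error(split_train_test(c(TRUE, rep(FALSE, 50))), "at least 2")
})

test_that("confusion metrics follow their closed forms", {
  cm <- confusion_matrix(c(rep(TRUE, 10), rep(FALSE, 10)),
                         c(rep(TRUE, 9), FALSE, rep(FALSE, 8), TRUE, TRUE))
  expect_equal(cm$tp, 9); expect_equal(cm$fn, 1)
  expect_equal(cm$tn, 8); expect_equal(cm$fp, 2)
  m <- compute_metrics(cm)
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$f1, 18 / 21, tolerance = 1e-12)

  perfect <- compute_metrics(confusion_matrix(c(TRUE, FALSE), c(TRUE, FALSE)))
  expect_true(all(unlist(perfect) == 1))

  # all-negative predictor on imbalanced data
  truth <- c(rep(TRUE, 3), rep(FALSE, 97))
  m0 <- compute_metrics(confusion_matrix(truth, rep(FALSE, 100)))
  expect_equal(m0$sensitivity, 0)
  expect_equal(m0$accuracy, 0.97)

  expect_error(compute_metrics(confusion_matrix(rep(FALSE, 5), rep(FALSE, 5))),
               "undefined metric")
})

test_that("metric algebra: accuracy is the prevalence-weighted mix", {
  set.seed(601)
  for (rep in 1:10) {
    truth <- runif(60) < 0.3
    if (!any(truth) || all(truth)) next
    pred <- runif(60) < 0.5
    m <- compute_metrics(confusion_matrix(truth, pred))
    prev <- mean(truth)
    expect_equal(m$accuracy, prev * m$sensitivity + (1 - prev) * m$specificity,
                 tolerance = 1e-12)
  }
})

test_that("ROC endpoints, monotonicity and degenerate score orderings", {
  lab <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(roc_auc(lab, as.numeric(lab))$auc, 1.0)
  expect_equal(roc_auc(lab, 1 - as.numeric(lab))$auc, 0.0)
  expect_error(roc_auc(rep(TRUE, 4), runif(4)), "both classes")

  set.seed(602)
  for (rep in 1:10) {
    lab <- runif(25) < 0.4
    if (!any(lab) || all(lab)) next
    sc <- round(runif(25), 1)  # coarse scores force ties
    r <- roc_auc(lab, sc)
    expect_equal(r$points$fpr[1], 0); expect_equal(r$points$tpr[1], 0)
    expect_equal(r$points$fpr[nrow(r$points)], 1)
    expect_equal(r$points$tpr[nrow(r$points)], 1)
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$tpr) >= 0))
  }
})

test_that("trapezoid AUC equals the Mann-Whitney pair count", {
  # hand-listed six pairs with one tie
  lab <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  sc <- c(0.9, 0.7, 0.4, 0.4, 0.3, 0.1)
  # pairs: (0.9,{.4,.3,.1}) 3 wins; (0.7,...) 3 wins; (0.4 vs .4 tie=0.5,
  # vs .3, .1 wins) => 8.5 / 9
  expect_equal(roc_auc(lab, sc)$auc, 8.5 / 9, tolerance = 1e-12)
  expect_equal(mann_whitney_auc(lab, sc), 8.5 / 9)

  set.seed(603)
  for (rep in 1:20) {
    n <- sample(6:30, 1)
    lab <- runif(n) < 0.5
    if (!any(lab) || all(lab)) next
    sc <- sample(seq(0, 1, 0.05), n, replace = TRUE)
    expect_equal(roc_auc(lab, sc)$auc, mann_whitney_auc(lab, sc),
                 tolerance = 1e-12)
  }
})

test_that("the ablation grid completes, is bookkept and matches direct runs", {
  cfg <- screened_config(700, 0.15, seed = 19)
  corpus <- make_corpus(cfg)

  # a one-cell grid at defaults equals a direct classifier run
  g1 <- tibble::tibble(stopwords = TRUE, ngram_order = 2L, smote = TRUE,
                       n_trees = 250L)
  res1 <- run_ablation(corpus, g1, cfg)
  direct <- run_classifier(corpus, cfg)$report
  expect_equal(res1$sensitivity, direct$sensitivity)
  expect_equal(res1$auc, direct$auc)

  # five tree counts -> five rows, fingerprints all distinct
  g5 <- ablation_grid(stopwords = TRUE, ngram_order = 2L, smote = TRUE,
                      n_trees = c(100L, 150L, 200L, 250L, 300L))
  res5 <- run_ablation(corpus, g5, cfg)
  expect_equal(nrow(res5), 5L)
  expect_true(all(is.na(res5$error)))
  expect_equal(length(unique(res5$fingerprint)), 5L)

  # a failing cell is recorded without aborting the grid
  gbad <- tibble::tibble(stopwords = c(TRUE, TRUE),
                         ngram_order = c(2L, 50L),  # 50-grams prune to nothing
                         smote = TRUE, n_trees = 50L)
  resb <- run_ablation(corpus, gbad, cfg)
  expect_true(is.na(resb$error[1]))
  expect_false(is.na(resb$error[2]))

  csv <- withr::local_tempfile(fileext = ".csv")
  write_ablation_csv(res5, csv)
  expect_equal(nrow(utils::read.csv(csv)), 5)
})
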