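test_that("SMOTE interpolation stays on minority segments", {
  # two points: every synthetic sample must satisfy x_new = x_min + l (x_nb - x_min)
  two <- rbind(c(0, 0), c(2, 4))
  syn <- smote_oversample(two, 200, smote_config(k_neighbors = 1, seed = 5))
  expect_equal(nrow(syn), 200)
  lambda <- syn[, 1] / 2
  expect_true(all(lambda >= 0 & lambda <= 1))
  expect_equal(syn[, 2], 4 * lambda, tolerance = 1e-12)  # colinear coordinates
  # lambda actually spans the unit interval (endpoints approachable)
  expect_lt(min(lambda), 0.05)
  expect_gt(max(lambda), 0.95)

  # general case: each synthetic row lies on a segment between two real rows
  set.seed(501)
  x <- matrix(rnorm(40 * 6), 40, 6)
  syn <- smote_oversample(x, 60, smote_config(k_neighbors = 5, seed = 6))
  on_segment <- function(s) {
    for (i in 1:39) for (j in (i + 1):40) {
      d <- x[j, ] - x[i, ]
      nz <- which(abs(d) > 1e-12)
      lam <- (s[nz] - x[i, nz]) / d[nz]
      if (max(lam) - min(lam) < 1e-9 &&
          lam[1] >= -1e-9 && lam[1] <= 1 + 1e-9 &&
          max(abs(s - (x[i, ] + lam[1] * d))) < 1e-9) return(TRUE)
    }
    FALSE
  }
  expect_true(all(apply(syn, 1, on_segment)))

  # bounding box (convexity) property
  expect_true(all(sweep(syn, 2, apply(x, 2, max), "<=")))
  expect_true(all(sweep(syn, 2, apply(x, 2, min), ">=")))

  expect_error(smote_oversample(x[1, , drop = FALSE], 5), "at least 2")
})

test_that("balancing raises the minority to the target ratio, originals first", {
  set.seed(502)
  x <- matrix(rnorm(110 * 4), 110, 4)
  y <- c(rep(TRUE, 10), rep(FALSE, 100))
  bal <- balance_dataset(x, y, smote_config(seed = 7))
  expect_equal(sum(bal$labels), 100)
  expect_equal(sum(!bal$labels), 100)
  expect_equal(bal$n_synthetic, 90L)
  # original rows preserved, in order, before synthetics
  expect_equal(bal$features[1:110, ], x, ignore_attr = TRUE)
  expect_equal(bal$labels[1:110], y)

  # already balanced input is unchanged
  yb <- rep(c(TRUE, FALSE), each = 55)
  bal2 <- balance_dataset(x, yb)
  expect_equal(bal2$n_synthetic, 0L)
  expect_equal(bal2$features, x, ignore_attr = TRUE)

  expect_error(balance_dataset(x, rep(TRUE, 110)), "both classes")
})

test_that("gini impurity follows the closed form and is maximal at uniform", {
  expect_equal(gini_impurity(1), 0)
  expect_equal(gini_impurity(c(0.5, 0.5)), 0.5)
  expect_equal(gini_impurity(c(0.9, 0.1)), 0.18)
  expect_error(gini_impurity(c(0.7, 0.2)), "sum to 1")
  expect_error(gini_impurity(c(1.2, -0.2)), "non-negative")

  set.seed(503)
  for (C in 2:5) {
    uni <- gini_impurity(rep(1 / C, C))
    expect_equal(uni, 1 - 1 / C)
    for (rep in 1:20) {
      p <- runif(C); p <- p / sum(p)
      expect_lte(gini_impurity(p), uni + 1e-12)
    }
  }
})

test_that("forest training is seeded, separable data are learned, errors are raised", {
  set.seed(504)
  x <- matrix(rnorm(200 * 8), 200, 8)
  colnames(x) <- sprintf("f%02d", 1:8)
  y <- x[, 1] > 0          # one perfectly separating feature
  x[, 1] <- as.numeric(y)  # make it binary and exact

  cfgf <- forest_config(n_trees = 100, mtry = 4, seed = 17)
  m1 <- train_forest(x, y, cfgf)
  m2 <- train_forest(x, y, cfgf)
  p1 <- predict(m1, x)
  p2 <- predict(m2, x)
  expect_identical(p1$scores, p2$scores)

  # training accuracy 1.0 and confident scores on the separable problem
  expect_equal(mean(p1$labels == y), 1.0)
  expect_true(all(p1$scores[y] >= 0.9))

  # labels are the thresholded scores, ties going positive
  expect_identical(p1$labels, p1$scores >= cfgf$vote_threshold)

  expect_error(train_forest(x, y, forest_config(mtry = 50)), "mtry")
  expect_error(train_forest(x, rep(TRUE, 200)), "both classes")
  expect_error(predict(m1, x[, 1:5]), "mismatch")
})

test_that("the forest agrees with an independent reference ensemble", {
  skip_if_not_installed("randomForest")
  # 200 x 20 task whose classes are separated by a margin, so that both
  # ensembles agree away from the decision boundary
  set.seed(505)
  x0 <- matrix(rnorm(600 * 20), 600, 20)
  colnames(x0) <- sprintf("f%02d", 1:20)
  s0 <- x0[, 1] + 0.8 * x0[, 2]
  keep <- abs(s0) > 0.6
  x <- x0[keep, ][1:200, ]
  y <- (s0[keep] > 0)[1:200]
  xt0 <- matrix(rnorm(3000 * 20), 3000, 20)
  colnames(xt0) <- colnames(x)
  st <- xt0[, 1] + 0.8 * xt0[, 2]
  xt <- xt0[abs(st) > 0.6, ][1:200, ]

  ours <- predict(train_forest(x, y, forest_config(n_trees = 250, mtry = 2,
                                                   seed = 31)), xt)
  ref <- randomForest::randomForest(x = x, y = factor(y), ntree = 250, mtry = 2)
  ref_lab <- predict(ref, xt) == "TRUE"
  expect_lt(mean(ours$labels != ref_lab), 0.02)
})

test_that("removing SMOTE collapses sensitivity on extreme imbalance", {
  cfg <- screened_config(1600, 0.03, seed = 5, misspelling_rate = 0.5,
                         negation_distractor_rate = 0.5,
                         include_size_sentence = FALSE)
  corpus <- make_corpus(cfg)
  on <- cfg; on$smote$enabled <- TRUE
  off <- cfg; off$smote$enabled <- FALSE
  sens_on <- run_classifier(corpus, on)$report$sensitivity
  sens_off <- run_classifier(corpus, off)$report$sensitivity
  expect_lt(sens_off, sens_on)
})
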