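#' SMOTE configuration
#'
#' @param k_neighbors Number of nearest minority neighbours considered
#'   when interpolating (conventional default 5).
#' @param target_ratio Desired minority:majority ratio after
#'   oversampling, in (0, 1\]; 1 means a fully balanced 1:1 set.
#' @param seed Integer seed.
#' @return List of class `smote_config`.
#' @export
smote_config <- function(k_neighbors = 5L, target_ratio = 1, seed = 1L) {
  if (!is.numeric(k_neighbors) || k_neighbors < 1) {
    stop_invalid("k_neighbors must be >= 1")
  }
  if (!is.numeric(target_ratio) || target_ratio <= 0 || target_ratio > 1) {
    stop_invalid("target_ratio must lie in (0, 1]")
  }
  structure(list(k_neighbors = as.integer(k_neighbors),
                 target_ratio = target_ratio, seed = as.integer(seed)),
            class = "smote_config")
}

#' Synthetic minority oversampling (SMOTE)
#'
#' Generates `n_synthetic` new minority-class feature vectors by the
#' interpolation rule
#' \deqn{x_{new} = x_{minority} + \lambda (x_{neighbor} - x_{minority})}
#' where `x_minority` is a uniformly chosen minority row, `x_neighbor` one
#' of its `k` Euclidean nearest minority neighbours (chosen uniformly) and
#' \eqn{\lambda \sim U(0, 1)}. Every synthetic row therefore lies on a
#' segment between two real minority samples. Interpolation output is
#' real-valued even over integer count features; no rounding is applied.
#'
#' @param minority_rows Numeric matrix of minority-class feature vectors
#'   (rows = samples); at least 2 rows.
#' @param n_synthetic Number of synthetic rows to generate.
#' @param config A [smote_config()]. `k_neighbors` is truncated to the
#'   number of available neighbours when it exceeds `nrow - 1`.
#' @return Numeric matrix with `n_synthetic` rows.
#' @export
smote_oversample <- function(minority_rows, n_synthetic, config = smote_config()) {
  minority_rows <- as.matrix(minority_rows)
  m <- nrow(minority_rows)
  if (m < 2L) {
    stop_invalid("cannot oversample: need at least 2 minority rows, got %d", m)
  }
  if (n_synthetic == 0L) {
    return(minority_rows[0, , drop = FALSE])
  }
  k <- min(config$k_neighbors, m - 1L)
  d <- as.matrix(stats::dist(minority_rows))
  diag(d) <- Inf
  # k nearest neighbours per row (ties broken by index, deterministic)
  nn <- matrix(0L, nrow = m, ncol = k)
  for (i in seq_len(m)) nn[i, ] <- order(d[i, ])[seq_len(k)]
  withr::with_seed(config$seed, {
    base <- sample.int(m, n_synthetic, replace = TRUE)
    pick <- sample.int(k, n_synthetic, replace = TRUE)
    lambda <- runif(n_synthetic)
    neigh <- nn[cbind(base, pick)]
    xb <- minority_rows[base, , drop = FALSE]
    xn <- minority_rows[neigh, , drop = FALSE]
    out <- xb + lambda * (xn - xb)
  })
  rownames(out) <- sprintf("synthetic%06d", seq_len(n_synthetic))
  out
}

#' Rebalance a training set with SMOTE
#'
#' Raises the minority-class count to `round(target_ratio * majority)` by
#' appending synthetic rows; majority rows are untouched and all original
#' rows come first, in their original order. Already-balanced input is
#' returned unchanged.
#'
#' @param features Numeric matrix (rows = samples).
#' @param labels Logical vector (or 2-level factor) aligned with rows.
#' @param config A [smote_config()].
#' @return List with `features`, `labels`, `n_synthetic`.
#' @export
balance_dataset <- function(features, labels, config = smote_config()) {
  features <- as.matrix(features)
  if (is.factor(labels)) labels <- labels == levels(labels)[2]
  labels <- as.logical(labels)
  stopifnot(nrow(features) == length(labels))
  tab <- table(labels)
  if (length(tab) < 2L) {
    stop_invalid("both classes must be present to balance")
  }
  minority_is_pos <- tab[["TRUE"]] < tab[["FALSE"]]
  min_mask <- if (minority_is_pos) labels else !labels
  n_min <- sum(min_mask)
  n_maj <- sum(!min_mask)
  n_target <- round(config$target_ratio * n_maj)
  n_syn <- n_target - n_min
  if (n_syn <= 0L) {
    return(list(features = features, labels = labels, n_synthetic = 0L))
  }
  syn <- smote_oversample(features[min_mask, , drop = FALSE], n_syn, config)
  list(features = rbind(features, syn),
       labels = c(labels, rep(minority_is_pos, n_syn)),
       n_synthetic = as.integer(n_syn))
}

#' Gini impurity of a class distribution
#'
#' \deqn{Gini = 1 - \sum_i p_i^2,} the split-selection criterion
#' minimized at each tree node. Zero for a pure node; maximal
#' (\eqn{1 - 1/C}) at the uniform distribution over `C` classes.
#'
#' @param proportions Numeric vector of class proportions, non-negative
#'   and summing to 1 (tolerance 1e-9).
#' @return Gini impurity in \[0, 1 - 1/C\].
#' @export
gini_impurity <- function(proportions) {
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-9) {
    stop_invalid("proportions must be non-negative and sum to 1")
  }
  1 - sum(proportions^2)
}
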