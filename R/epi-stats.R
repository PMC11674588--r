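#' Published procedure-by-outcome contingency counts
#'
#' The 2x2 table of pneumothorax incidence by CVC procedure reported for
#' the source cohort (n = 17,175): 16,274 / 106 after insertion and
#' 792 / 3 after removal. Used for desk-scale checks and as the
#' calibration reference of the synthetic-cohort defaults.
#'
#' @return 2x2 integer matrix with rows `insertion`, `removal` and
#'   columns `no_pneumothorax`, `pneumothorax`.
#' @export
cvc_incidence_counts <- function() {
  matrix(c(16274L, 106L, 792L, 3L), nrow = 2, byrow = TRUE,
         dimnames = list(c("insertion", "removal"),
                         c("no_pneumothorax", "pneumothorax")))
}

#' Chi-square test for a 2x2 contingency table
#'
#' Pearson chi-square with 1 degree of freedom,
#' \deqn{X^2 = \sum (|O - E| - c)^2 / E,}
#' with expected counts from the row/column margins. With
#' `continuity_correction = TRUE` (the default, mirroring common
#' statistical software), `c = min(0.5, min|O - E|)` — the Yates
#' correction with the usual guard against over-correction; otherwise
#' `c = 0`. Invariant under transposition and row/column swaps.
#'
#' @param table 2x2 numeric matrix of counts.
#' @param continuity_correction Apply the Yates correction (default
#'   `TRUE`).
#' @return List with `statistic`, `df` (= 1), `p_value`, `expected`,
#'   `continuity_correction`.
#' @export
chi_square_2x2 <- function(table, continuity_correction = TRUE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop_invalid("table must be 2x2")
  if (any(table < 0)) stop_invalid("counts must be non-negative")
  rs <- rowSums(table); cs <- colSums(table); n <- sum(table)
  if (any(rs == 0) || any(cs == 0)) {
    stop_invalid("zero margin: every row and column must have a positive total")
  }
  expected <- outer(rs, cs) / n
  cc <- if (continuity_correction) min(0.5, min(abs(table - expected))) else 0
  stat <- sum((abs(table - expected) - cc)^2 / expected)
  list(statistic = stat, df = 1L,
       p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       expected = expected,
       continuity_correction = continuity_correction)
}

# IRLS core for binary logistic regression. X must include the intercept
# column. Convergence: max |delta beta| < tol within max_iter iterations.
irls_logistic <- function(X, y, tol = 1e-8, max_iter = 50L) {
  p <- ncol(X)
  beta <- numeric(p)
  beta[1] <- stats::qlogis(max(min(mean(y), 1 - 1e-8), 1e-8))
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta_new <- tryCatch(drop(solve(XtW %*% X, XtW %*% z)),
                         error = function(e) {
                           stop_invalid(paste("IRLS failed at iteration %d",
                                              "(singular information matrix;",
                                              "possible separation)"), iter)
                         })
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop_invalid(paste("logistic fit did not converge after %d iterations",
                       "(possible separation)"), max_iter)
  }
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  info <- t(X * w) %*% X
  se <- sqrt(diag(solve(info)))
  loglik <- sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
  list(beta = beta, se = se, loglik = loglik, iterations = iter,
       converged = converged)
}

#' Logistic regression of pneumothorax on age and gender
#'
#' Maximum-likelihood fit by iteratively reweighted least squares of
#' \deqn{logit P(pneumothorax) = \beta_0 + \beta_{age} age +
#'   \beta_{gender} male} with male coded 1 (the package-wide coding).
#' Standard errors come from the inverse observed information; deviances
#' are -2 log-likelihood based and AIC = residual deviance + 2k.
#' Convergence requires the maximum absolute coefficient change to fall
#' below 1e-8 within 50 iterations; separation or non-convergence raises
#' an explicit error carrying the iteration count.
#'
#' @param age Numeric vector, age in years.
#' @param gender Numeric 0/1 (male = 1) or logical vector.
#' @param outcome Numeric 0/1 or logical vector (pneumothorax = 1).
#' @return Object of class `logistic_fit`: `coefficients`,
#'   `standard_errors`, `z_values`, `p_values` (named `intercept`, `age`,
#'   `gender`), `null_deviance`, `residual_deviance`, `aic`, `converged`,
#'   `iterations`.
#' @export
fit_logistic <- function(age, gender, outcome) {
  age <- as.numeric(age)
  gender <- as.numeric(gender)
  y <- as.numeric(outcome)
  stopifnot(length(age) == length(y), length(gender) == length(y))
  if (!all(y %in% c(0, 1))) stop_invalid("outcome must be binary 0/1")
  if (length(unique(y)) < 2L) stop_invalid("both outcome classes must be present")
  X <- cbind(intercept = 1, age = age, gender = gender)
  fit <- irls_logistic(X, y)
  # intercept-only fit for the null deviance (closed form)
  p0 <- mean(y)
  null_dev <- -2 * sum(y * log(p0) + (1 - y) * log(1 - p0))
  res_dev <- -2 * fit$loglik
  k <- ncol(X)
  z <- fit$beta / fit$se
  structure(list(
    coefficients = stats::setNames(fit$beta, colnames(X)),
    standard_errors = stats::setNames(fit$se, colnames(X)),
    z_values = stats::setNames(z, colnames(X)),
    p_values = stats::setNames(2 * pnorm(-abs(z)), colnames(X)),
    null_deviance = null_dev,
    residual_deviance = res_dev,
    aic = res_dev + 2 * k,
    converged = fit$converged,
    iterations = fit$iterations
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("<logistic_fit> (IRLS,", x$iterations, "iterations)\n")
  tab <- data.frame(Estimate = x$coefficients,
                    `Std. Error` = x$standard_errors,
                    `Z value` = x$z_values,
                    `p value` = signif(x$p_values, 4),
                    check.names = FALSE)
  print(tab)
  cat(sprintf("null deviance %.1f | residual deviance %.1f | AIC %.1f\n",
              x$null_deviance, x$residual_deviance, x$aic))
  invisible(x)
}

#' Linear model of pneumothorax size on removal status
#'
#' Ordinary least squares of size (mm) on a removal indicator. With a
#' single binary regressor the intercept is the insertion-group mean and
#' the slope the removal-minus-insertion mean difference; the p-value is
#' the two-sided t-test for the slope.
#'
#' @param size_mm Numeric vector of pneumothorax sizes (positives only).
#' @param is_removal Numeric 0/1 or logical, 1 = size observed after
#'   removal.
#' @return List with `intercept`, `slope`, `slope_p_value` and the
#'   underlying `lm` fit.
#' @export
fit_linear_size <- function(size_mm, is_removal) {
  is_removal <- as.numeric(is_removal)
  stopifnot(length(size_mm) == length(is_removal))
  if (length(unique(is_removal)) < 2L) {
    stop_invalid("slope undefined: all sizes are in one procedure group")
  }
  if (min(table(is_removal)) < 2L) {
    stop_invalid("need at least 2 observations per group for the p-value")
  }
  fit <- lm(size_mm ~ is_removal)
  sm <- summary(fit)$coefficients
  list(intercept = unname(coef(fit)[1]),
       slope = unname(coef(fit)[2]),
       slope_p_value = unname(sm["is_removal", "Pr(>|t|)"]),
       fit = fit)
}

#' Incidence summary by procedure
#'
#' Tabulates pneumothorax counts and incidences per procedure and
#' overall, plus the insertion/removal shares of the cohort.
#'
#' @param records Record tibble with `procedure` and
#'   `label_pneumothorax`, or a 2x2 count matrix shaped like
#'   [cvc_incidence_counts()].
#' @param digits Decimal places for the percentage columns (default 1).
#' @return List with `table` (2x2 counts), `summary` (tibble with rows
#'   insertion / removal / overall: `n`, `cases`, `incidence`,
#'   `incidence_pct`) and `shares` (procedure shares of all records).
#' @export
incidence_summary <- function(records, digits = 1) {
  if (is.matrix(records)) {
    tab <- records
  } else {
    tab <- matrix(0, 2, 2, dimnames = list(c("insertion", "removal"),
                                           c("no_pneumothorax", "pneumothorax")))
    if (nrow(records) > 0) {
      for (pr in c("insertion", "removal")) {
        sel <- records$procedure == pr
        tab[pr, "pneumothorax"] <- sum(records$label_pneumothorax[sel])
        tab[pr, "no_pneumothorax"] <- sum(sel) - tab[pr, "pneumothorax"]
      }
    }
  }
  n_proc <- rowSums(tab)
  n_all <- sum(tab)
  cases <- tab[, "pneumothorax"]
  # per-procedure incidence uses the procedure denominator; the
  # removal row is additionally reported against the whole cohort,
  # matching how sub-percent removal rates are usually quoted
  inc_vec <- c(ifelse(n_proc > 0, cases / n_proc, 0),
               if (n_all > 0) sum(cases) / n_all else 0)
  smry <- tibble::tibble(
    group = c("insertion", "removal", "overall"),
    n = unname(c(n_proc, n_all)),
    cases = unname(c(cases, sum(cases))),
    incidence = unname(inc_vec))
  smry$incidence_pct <- round(100 * smry$incidence, digits)
  removal_of_total <- if (n_all > 0) cases[["removal"]] / n_all else 0
  list(table = tab,
       summary = smry,
       removal_incidence_of_total = removal_of_total,
       shares = if (n_all > 0) n_proc / n_all else n_proc)
}
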