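#' @importFrom stats pnorm qnorm dnorm plogis rbinom runif pchisq lm
#' @importFrom stats coef uniroot predict
#' @importFrom withr with_seed
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

is_prop <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1

# Truncated-normal helpers (inverse-CDF sampling; closed-form moments used
# for calibration and for the prevalence integral).
rtruncnorm <- function(n, mean, sd, lower, upper) {
  pa <- pnorm(lower, mean, sd)
  pb <- pnorm(upper, mean, sd)
  qnorm(runif(n, pa, pb), mean, sd)
}

truncnorm_mean <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- pnorm(b) - pnorm(a)
  mean + sd * (dnorm(a) - dnorm(b)) / z
}

truncnorm_density <- function(x, mean, sd, lower, upper) {
  z <- pnorm(upper, mean, sd) - pnorm(lower, mean, sd)
  out <- dnorm(x, mean, sd) / z
  out[x < lower | x > upper] <- 0
  out
}

# Recursive config merge: values in `override` win, lists merge by name.
merge_config <- function(base, override) {
  if (is.null(override)) return(base)
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}
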