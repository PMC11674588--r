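#' Cohort generator parameters
#'
#' Bundles everything needed to simulate a cohort of post-CVC chest X-ray
#' records: cohort size, procedure mix, demographics, and the logistic
#' outcome model for pneumothorax.
#'
#' Defaults reproduce the structure of the source cohort: 95.4% insertions,
#' 54.5% male, ages on \[18, 101\] from a truncated normal calibrated to
#' mean 66.64 / median 69 years, and outcome probabilities from the fitted
#' risk model logit(p) = intercept + beta_age * age + beta_gender * male,
#' with male coded 1 (the reference coding used throughout this package).
#' Pneumothorax sizes (mm) are drawn, for positive records only, from a
#' truncated normal(40, 25) clipped to \[2, 140\].
#'
#' @param n_records Positive integer, number of records to generate.
#' @param insertion_fraction Proportion of records that are CVC insertions.
#' @param male_fraction Proportion of male patients.
#' @param age_distribution List with `mean`, `sd`, `min`, `max` describing a
#'   truncated normal for age in years.
#' @param outcome_model List with `intercept`, `beta_age` (log-odds per
#'   year), `beta_gender` (log-odds for male = 1).
#' @param size_distribution List with `mean`, `sd`, `min`, `max` for
#'   pneumothorax size in mm.
#' @param hours_range Length-2 numeric, range of hours between procedure and
#'   X-ray; uniform sampling. The default \[0, 24\] deliberately straddles
#'   the 12-hour inclusion window so that [apply_exclusions()] has records
#'   to remove.
#' @param department_weights Named numeric vector of admission-department
#'   sampling weights.
#' @param seed Integer seed; the generator is fully reproducible.
#' @return A validated list of class `cohort_params`.
#' @seealso [generate_cohort()], [expected_prevalence()]
#' @export
cohort_params <- function(n_records,
                          insertion_fraction = 16380 / 17175,
                          male_fraction = 0.545,
                          age_distribution = list(mean = 84.259, sd = 41.288,
                                                  min = 18, max = 101),
                          outcome_model = list(intercept = -4.396298,
                                               beta_age = -0.011809,
                                               beta_gender = 0.200964),
                          size_distribution = list(mean = 40, sd = 25,
                                                   min = 2, max = 140),
                          hours_range = c(0, 24),
                          department_weights = c(
                            "internal medicine" = 0.526,
                            "neurology" = 0.109,
                            "surgery" = 0.083,
                            "neurosurgery" = 0.051,
                            "trauma and orthopedics" = 0.065,
                            "vascular surgery" = 0.040,
                            "other" = 0.126),
                          seed = 1L) {
  if (!is.numeric(n_records) || length(n_records) != 1L || is.na(n_records) ||
      n_records <= 0 || n_records != floor(n_records)) {
    stop_invalid("n_records must be a positive integer, got %s",
                 deparse(substitute(n_records)))
  }
  if (!is_prop(insertion_fraction)) stop_invalid("insertion_fraction must lie in [0,1]")
  if (!is_prop(male_fraction)) stop_invalid("male_fraction must lie in [0,1]")
  for (fld in c("intercept", "beta_age", "beta_gender")) {
    if (!is.numeric(outcome_model[[fld]])) {
      stop_invalid("outcome_model$%s must be numeric", fld)
    }
  }
  for (d in list(age_distribution, size_distribution)) {
    if (!all(c("mean", "sd", "min", "max") %in% names(d))) {
      stop_invalid("distribution specs need mean, sd, min, max")
    }
    if (d$sd <= 0 || d$min >= d$max) stop_invalid("invalid distribution spec")
  }
  if (length(hours_range) != 2L || hours_range[1] < 0 ||
      hours_range[1] > hours_range[2]) {
    stop_invalid("hours_range must be a non-negative increasing pair")
  }
  structure(list(
    n_records = as.integer(n_records),
    insertion_fraction = insertion_fraction,
    male_fraction = male_fraction,
    age_distribution = age_distribution,
    outcome_model = outcome_model,
    size_distribution = size_distribution,
    hours_range = hours_range,
    department_weights = department_weights / sum(department_weights),
    seed = as.integer(seed)
  ), class = "cohort_params")
}

#' Generate a synthetic cohort (metadata only)
#'
#' Draws `n_records` imaging events. Ages come from the configured truncated
#' normal (rounded to whole years and clamped to its support), gender and
#' procedure are Bernoulli draws, and the pneumothorax label is drawn
#' per-record as Bernoulli(plogis(intercept + beta_age * age +
#' beta_gender * male)). Sizes in mm are attached only to positive records.
#' Report and request texts are left empty; see [generate_corpus()].
#'
#' @param params A [cohort_params()] object.
#' @return A tibble with one row per record (columns: `record_id`,
#'   `report_text`, `request_text`, `age_years`, `gender`, `procedure`,
#'   `hours_since_procedure`, `department`, `label_pneumothorax`,
#'   `pneumothorax_size_mm`, `contraindication_present`,
#'   `incorrect_placement`, `follow_up`).
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  n <- params$n_records
  ad <- params$age_distribution
  sd_ <- params$size_distribution
  om <- params$outcome_model
  withr::with_seed(params$seed, {
    age_cont <- rtruncnorm(n, ad$mean, ad$sd, ad$min, ad$max)
    age <- as.integer(pmin(pmax(round(age_cont), ad$min), ad$max))
    male <- runif(n) < params$male_fraction
    procedure <- ifelse(runif(n) < params$insertion_fraction,
                        "insertion", "removal")
    hours <- runif(n, params$hours_range[1], params$hours_range[2])
    dept <- sample(names(params$department_weights), n, replace = TRUE,
                   prob = params$department_weights)
    p <- plogis(om$intercept + om$beta_age * age + om$beta_gender * male)
    label <- runif(n) < p
    size <- rep(NA_real_, n)
    npos <- sum(label)
    if (npos > 0) {
      size[label] <- pmin(pmax(rtruncnorm(npos, sd_$mean, sd_$sd,
                                          sd_$min, sd_$max),
                               sd_$min), sd_$max)
    }
    tibble::tibble(
      record_id = sprintf("R%06d", seq_len(n)),
      report_text = "",
      request_text = "",
      age_years = age,
      gender = ifelse(male, "male", "female"),
      procedure = procedure,
      hours_since_procedure = hours,
      department = dept,
      label_pneumothorax = label,
      pneumothorax_size_mm = size,
      contraindication_present = FALSE,
      incorrect_placement = FALSE,
      follow_up = FALSE
    )
  })
}

#' Expected pneumothorax prevalence under the outcome model
#'
#' Computes E\[plogis(intercept + beta_age * age + beta_gender * male)\] by
#' numerical integration over the configured truncated-normal age density
#' and the gender mixture. This is the deterministic counterpart of the
#' Monte-Carlo prevalence of [generate_cohort()] and is also used to
#' calibrate benchmark intercepts.
#'
#' @param params A [cohort_params()] object (its `n_records` is ignored).
#' @param intercept Optional replacement intercept (defaults to the one in
#'   `params$outcome_model`).
#' @return Expected prevalence as a proportion.
#' @export
expected_prevalence <- function(params, intercept = NULL) {
  stopifnot(inherits(params, "cohort_params"))
  om <- params$outcome_model
  b0 <- intercept %||% om$intercept
  ad <- params$age_distribution
  ages <- seq(ad$min, ad$max, by = 0.05)
  w <- truncnorm_density(ages, ad$mean, ad$sd, ad$min, ad$max)
  w <- w / sum(w)
  p_male <- sum(w * plogis(b0 + om$beta_age * ages + om$beta_gender))
  p_female <- sum(w * plogis(b0 + om$beta_age * ages))
  params$male_fraction * p_male + (1 - params$male_fraction) * p_female
}

#' Calibrate the outcome-model intercept to a target prevalence
#'
#' Root-finds the intercept for which [expected_prevalence()] equals
#' `target_prevalence`, keeping the age and gender coefficients fixed.
#'
#' @param params A [cohort_params()] object.
#' @param target_prevalence Desired expected prevalence in (0, 1).
#' @return The calibrated intercept (log-odds).
#' @export
calibrate_outcome_intercept <- function(params, target_prevalence) {
  stopifnot(inherits(params, "cohort_params"),
            is_prop(target_prevalence), target_prevalence > 0,
            target_prevalence < 1)
  f <- function(b0) expected_prevalence(params, intercept = b0) - target_prevalence
  uniroot(f, lower = -20, upper = 10, tol = 1e-10)$root
}
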