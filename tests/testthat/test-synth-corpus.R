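test_that("cohort generation reproduces the configured demographic structure", {
  co <- generate_cohort(cohort_params(n_records = 17175, seed = 3))
  expect_equal(nrow(co), 17175)

  # male share 54.5% -> expected 9360 males, binomial 3 sigma ~ 196
  n_male <- sum(co$gender == "male")
  sigma <- sqrt(17175 * 0.545 * 0.455)
  expect_lt(abs(n_male - 17175 * 0.545), 3 * sigma)

  # ages constrained to [18, 101]; sample mean near the calibrated 66.64
  expect_true(all(co$age_years >= 18 & co$age_years <= 101))
  se_age <- sd(co$age_years) / sqrt(nrow(co))
  expect_lt(abs(mean(co$age_years) - 66.64), 3 * se_age + 0.5)  # +0.5 rounding to years

  # sizes present iff positive, inside [2, 140]
  expect_true(all(is.na(co$pneumothorax_size_mm) == !co$label_pneumothorax))
  sz <- co$pneumothorax_size_mm[co$label_pneumothorax]
  expect_true(all(sz >= 2 & sz <= 140))
})

test_that("outcome prevalence matches the numeric-integration oracle", {
  params <- cohort_params(n_records = 100000, seed = 11)
  co <- generate_cohort(params)
  prev_mc <- mean(co$label_pneumothorax)

  # independent oracle: integrate the inverse-logit against the truncated
  # normal age density with stats::integrate, mixing over gender
  ad <- params$age_distribution
  om <- params$outcome_model
  z <- pnorm(ad$max, ad$mean, ad$sd) - pnorm(ad$min, ad$mean, ad$sd)
  f <- function(a, g) plogis(om$intercept + om$beta_age * a + om$beta_gender * g) *
    dnorm(a, ad$mean, ad$sd) / z
  p_m <- integrate(f, ad$min, ad$max, g = 1)$value
  p_f <- integrate(f, ad$min, ad$max, g = 0)$value
  prev_oracle <- 0.545 * p_m + 0.455 * p_f

  expect_equal(prev_oracle, 0.00646, tolerance = 0.02)
  mc_se <- sqrt(prev_oracle * (1 - prev_oracle) / 100000)
  expect_lt(abs(prev_mc - prev_oracle), 4 * mc_se)
  # package integration agrees with the oracle
  expect_equal(expected_prevalence(params), prev_oracle, tolerance = 1e-4)
})

test_that("generation is deterministic for a fixed seed and validates inputs", {
  p <- cohort_params(n_records = 500, seed = 42)
  expect_identical(generate_cohort(p), generate_cohort(p))
  expect_error(cohort_params(n_records = 0), "positive integer")
  expect_error(cohort_params(n_records = 100, male_fraction = 1.4), "\\[0,1\\]")

  lex <- lexicon_config(seed = 9)
  co <- generate_cohort(cohort_params(n_records = 120, seed = 5))
  expect_identical(generate_corpus(co, lex), generate_corpus(co, lex))
})

test_that("reports carry the lexical phenomena their labels require", {
  lex0 <- lexicon_config(misspelling_rate = 0, abbreviation_rate = 0, seed = 2)
  lib <- pattern_library_from_lexicon(lex0)

  co <- generate_cohort(cohort_params(n_records = 250, seed = 21,
                                      hours_range = c(0, 12)))
  co$label_pneumothorax[1:60] <- TRUE   # force a block of positives
  co$pneumothorax_size_mm[1:60] <- 25
  co$label_pneumothorax[61:250] <- FALSE
  co$pneumothorax_size_mm[61:250] <- NA
  corpus <- generate_corpus(co, lex0)

  # zero noise: every positive report contains an exact affirmative phrase
  for (i in 1:10) {
    hits <- vapply(lex0$affirmative_phrases, grepl,
                   logical(1), x = corpus$report_text[i], fixed = TRUE)
    expect_true(any(hits))
  }

  # a distractor-saturated negative has a negated mention, no affirmative
  lex_d <- lexicon_config(negation_distractor_rate = 1, misspelling_rate = 0,
                          abbreviation_rate = 0, seed = 3)
  neg <- generate_report(co[200, ], lex_d)
  toks <- paste(normalize_text(neg$report_text), collapse = " ")
  m <- match_patterns(toks, lib)
  expect_true(any(m$category == "negated_pneumothorax"))
  expect_false(any(m$category == "affirmative_pneumothorax"))

  # contraindication injection rate is binomially calibrated and flagged
  lex_c <- lexicon_config(contraindication_rate = 0.2, seed = 4)
  big <- generate_cohort(cohort_params(n_records = 1000, seed = 31))
  big <- generate_corpus(big, lex_c)
  n_contra <- sum(big$contraindication_present)
  expect_lt(abs(n_contra - 200), 3 * sqrt(1000 * 0.2 * 0.8))

  expect_error(lexicon_config(affirmative_phrases = character(0)),
               "invalid lexicon")
})

test_that("corpus files round-trip and malformed input is reported by line", {
  cfg <- screened_config(80, 0.2, seed = 6)
  corpus <- make_corpus(cfg)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(corpus, path)
  back <- read_corpus(path)
  expect_equal(as.data.frame(back), as.data.frame(corpus))

  # empty corpus -> empty valid file
  write_corpus(corpus[0, ], path)
  expect_equal(nrow(read_corpus(path)), 0)

  # missing mandatory field named in the error, with its line number
  lines <- c('{"record_id":"R1","report_text":"x","request_text":"y","age_years":50,"gender":"male","procedure":"insertion","hours_since_procedure":1,"department":"other","label_pneumothorax":false}',
             '{"record_id":"R2","report_text":"x","age_years":50}')
  writeLines(lines, path)
  expect_error(read_corpus(path), "line 2.*request_text")

  csv <- withr::local_tempfile(fileext = ".csv")
  write_corpus_csv(corpus, csv)
  expect_equal(nrow(utils::read.csv(csv)), nrow(corpus))
})
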