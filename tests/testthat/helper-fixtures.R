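# Shared fixture builders; everything is generated in code, seeded.

# Small screened config (all records inside the 12-h window) with the
# outcome intercept calibrated to a target prevalence so classifier
# fixtures have enough positives to stratify on.
screened_config <- function(n_records, prevalence, seed = 1L,
                            misspelling_rate = 0,
                            negation_distractor_rate = 0.3,
                            include_size_sentence = TRUE) {
  cfg <- default_config(seed = seed, n_records = n_records)
  cfg$cohort$hours_range <- c(0, 12)
  base <- do.call(cohort_params, c(cfg$cohort, list(seed = 0L)))
  cfg$cohort$outcome_model$intercept <-
    calibrate_outcome_intercept(base, prevalence)
  cfg$lexicon$misspelling_rate <- misspelling_rate
  cfg$lexicon$negation_distractor_rate <- negation_distractor_rate
  cfg$lexicon$include_size_sentence <- include_size_sentence
  cfg
}

make_corpus <- function(cfg) {
  params <- do.call(cohort_params,
                    c(cfg$cohort, list(seed = cfg$seed + 101L)))
  generate_corpus(generate_cohort(params), test_lexicon(cfg))
}

test_lexicon <- function(cfg) {
  lexicon_config(language = cfg$language,
                 misspelling_rate = cfg$lexicon$misspelling_rate,
                 negation_distractor_rate = cfg$lexicon$negation_distractor_rate,
                 contraindication_rate = cfg$lexicon$contraindication_rate,
                 abbreviation_rate = cfg$lexicon$abbreviation_rate,
                 include_size_sentence = cfg$lexicon$include_size_sentence,
                 seed = cfg$seed + 211L)
}

# Random token corpus for DTM property tests.
random_token_corpus <- function(n_docs, vocab_size = 12, min_len = 0,
                                max_len = 15) {
  vocab <- sprintf("w%02d", seq_len(vocab_size))
  lapply(seq_len(n_docs), function(i) {
    len <- sample(min_len:max_len, 1)
    if (len == 0) character(0) else sample(vocab, len, replace = TRUE)
  })
}

# Brute-force Mann-Whitney AUC: P(s+ > s-) + 0.5 P(s+ = s-).
mann_whitney_auc <- function(labels, scores) {
  sp <- scores[labels]
  sn <- scores[!labels]
  tot <- 0
  for (p in sp) for (q in sn) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(sp) * length(sn))
}
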