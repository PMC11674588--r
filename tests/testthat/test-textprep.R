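test_that("normalize_text applies lowercase, punctuation and stopword rules", {
  expect_equal(normalize_text("Kein Pneumothorax."), c("kein", "pneumothorax"))
  expect_equal(normalize_text(""), character(0))
  expect_equal(normalize_text(NA_character_), character(0))
  expect_equal(normalize_text("Pneu, re. apikal 2 cm", stopwords = "re"),
               c("pneu", "apikal", "2", "cm"))

  # idempotence over generated report text
  lex <- lexicon_config(misspelling_rate = 0.3, seed = 8)
  co <- make_corpus(screened_config(40, 0.3, seed = 8, misspelling_rate = 0.3))
  sw <- default_stopwords("de")
  for (txt in co$report_text[1:20]) {
    once <- normalize_text(txt, sw)
    twice <- normalize_text(paste(once, collapse = " "), sw)
    expect_identical(once, twice)
  }
})

test_that("canonicalize_tokens maps abbreviations onto canonical lexemes", {
  map <- list(pneumothorax = c("pneu", "ptx"))
  expect_equal(canonicalize_tokens(c("kein", "ptx", "rechts", "pneu"), map),
               c("kein", "pneumothorax", "rechts", "pneumothorax"))
  expect_equal(canonicalize_tokens(character(0), map), character(0))
})

test_that("match_patterns reports spans with negation precedence", {
  lib <- pattern_library_from_lexicon(lexicon_config())

  m <- match_patterns("pneumothorax apikal", lib)
  expect_equal(m$category, "affirmative_pneumothorax")
  expect_equal(m$start, 1L)
  expect_equal(m$match, "pneumothorax")

  m <- match_patterns("kein pneumothorax", lib)
  expect_equal(m$category, "negated_pneumothorax")
  expect_equal(nrow(m), 1L)

  m <- match_patterns("z n thorakotomie", lib)
  expect_equal(m$category, "contraindication")

  # contraindication phrase embedding a mention yields no affirmative hit
  m <- match_patterns("vorbekannter pneumothorax", lib)
  expect_equal(m$category, "contraindication")

  # affirmative and negated mentions in one text are both found
  m <- match_patterns("pneumothorax rechts apikal kein pleuraerguss ausschluss pneu",
                      lib)
  expect_setequal(m$category, c("affirmative_pneumothorax", "negated_pneumothorax"))

  expect_error(pattern_library(data.frame(category = "affirmative_pneumothorax",
                                          pattern = "(unclosed", label = "bad")),
               "does not compile")
  expect_error(pattern_library(data.frame(category = "nonsense",
                                          pattern = "x", label = "bad")),
               "unknown pattern categories")
})

test_that("the rule layer recovers labels exactly on noise-free corpora", {
  cfg <- screened_config(400, 0.2, seed = 12, misspelling_rate = 0,
                         negation_distractor_rate = 0.5)
  corpus <- make_corpus(cfg)
  lib <- pattern_library_from_lexicon(test_lexicon(cfg))
  pred <- vapply(seq_len(nrow(corpus)), function(i) {
    classify_rules(corpus$report_text[i], corpus$request_text[i], lib)
  }, logical(1))
  expect_identical(pred, corpus$label_pneumothorax)
})

test_that("shipped pattern and stopword files load and agree with the defaults", {
  pat <- system.file("extdata", "patterns_de.yaml", package = "pneumotext")
  sw <- system.file("extdata", "stopwords_de.txt", package = "pneumotext")
  lib <- read_pattern_library(pat, sw)
  expect_s3_class(lib, "pattern_library")
  expect_setequal(lib$stopwords, default_stopwords("de"))
  gen <- pattern_library_from_lexicon(lexicon_config())
  expect_setequal(lib$patterns$pattern, gen$patterns$pattern)
})

test_that("exclusion rules fire in fixed order with inclusive boundaries", {
  base <- make_corpus(screened_config(8, 0.3, seed = 13))

  rec <- base[1, ]
  rec$age_years <- 17L
  expect_equal(apply_exclusions(rec)$reason, "under_18")

  rec <- base[1, ]
  rec$age_years <- 18L
  rec$hours_since_procedure <- 12.0
  res <- apply_exclusions(rec)
  expect_true(res$included)

  rec <- base[1, ]
  rec$report_text <- NA_character_
  rec$age_years <- 17L  # missing_data precedes under_18
  expect_equal(apply_exclusions(rec)$reason, "missing_data")

  rec <- base[1, ]
  rec$hours_since_procedure <- 12.0001
  expect_equal(apply_exclusions(rec)$reason, "outside_12h")

  rec <- base[1, ]
  rec$incorrect_placement <- TRUE
  expect_equal(apply_exclusions(rec)$reason, "incorrect_placement")

  rec <- base[1, ]
  rec$follow_up <- TRUE
  expect_equal(apply_exclusions(rec)$reason, "follow_up")
})

test_that("exclusions remove exactly the injected violations", {
  corpus <- make_corpus(screened_config(120, 0.25, seed = 14))
  bad_age <- c(5, 17, 50)
  bad_hours <- c(8, 33, 77)
  bad_flag <- c(100, 111)
  corpus$age_years[bad_age] <- 16L
  corpus$hours_since_procedure[bad_hours] <- 13.5
  corpus$follow_up[bad_flag] <- TRUE
  res <- apply_exclusions(corpus)
  expect_setequal(which(!res$included), c(bad_age, bad_hours, bad_flag))
  expect_true(all(is.na(res$reason[res$included])))
})
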