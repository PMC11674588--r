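#' Normalize free text into a token sequence
#'
#' Lowercases, maps every non-alphanumeric character (punctuation,
#' hyphens, slashes) to a space, splits on whitespace and removes
#' stopwords, preserving token order. Digits and non-ASCII letters
#' (umlauts) are kept. Idempotent: normalizing the re-joined output
#' changes nothing.
#'
#' Note that negation cues ("kein", "no", "nicht") must not appear in the
#' stopword list, or negated mentions would collapse onto affirmative
#' ones; [default_stopwords()] honours this.
#'
#' @param raw Character scalar (may be empty or `NA`).
#' @param stopwords Character vector of lowercase tokens to drop.
#' @return Character vector of tokens (empty for empty input).
#' @export
normalize_text <- function(raw, stopwords = character()) {
  if (length(raw) != 1L || is.na(raw) || !nzchar(raw)) return(character(0))
  x <- tolower(raw)
  x <- gsub("[^\\p{L}\\p{N}]+", " ", x, perl = TRUE)
  tokens <- strsplit(trimws(x), " ", fixed = TRUE)[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (length(stopwords) > 0) tokens <- tokens[!(tokens %in% stopwords)]
  tokens
}

#' Default custom stopwords
#'
#' Emulates the clinician-curated custom stopword resource of the
#' detection workflow: generic function words plus the institution's
#' boilerplate vocabulary — normal-finding and procedural terms that
#' carry no information about pneumothorax (catheter position phrases,
#' cardiac/mediastinal descriptions, comparison-with-prior wording).
#' Negation cues ("kein", "keine", "nicht", "ohne", "ausschluss", "no",
#' "without"), laterality and finding terms are deliberately retained so
#' that negated mentions and located mentions survive preprocessing.
#' Curating boilerplate out of the vocabulary is what makes a
#' low-`mtry` forest workable: without it the document-term matrix is
#' dominated by boilerplate bi-grams.
#'
#' @param language `"de"` or `"en"`.
#' @return Character vector of lowercase stopword tokens.
#' @export
default_stopwords <- function(language = c("de", "en")) {
  language <- match.arg(language)
  if (language == "de") {
    c(# function words
      "der", "die", "das", "und", "im", "in", "am", "an", "auf", "bei",
      "mit", "zur", "zum", "des", "dem", "den", "ist", "sind", "sich",
      "bitte", "ueber", "nach", "von", "vor", "als", "bds",
      # procedural boilerplate
      "zvk", "einlage", "neuanlage", "anlage", "zug", "kontrolle",
      "lagekontrolle", "entfernung", "zustand",
      # anatomy / normal-finding boilerplate
      "vena", "cava", "superior", "jugularis", "interna",
      "katheterspitze", "projektion", "herz", "mediastinum",
      "regelrecht", "lunge", "beidseits", "ausreichend", "beluftet",
      "zwerchfellkuppen", "glatt", "begrenzt", "knoecherner", "thorax",
      "intakt", "vergleich", "voraufnahme", "unveraendert",
      "weichteile", "unauffaellig")
  } else {
    c(# function words
      "the", "a", "an", "and", "of", "with", "is", "are", "at", "on",
      "in", "over", "via", "please", "after", "for", "to",
      # procedural boilerplate
      "central", "line", "placed", "placement", "removal", "position",
      "check", "post", "study",
      # anatomy / normal-finding boilerplate
      "internal", "jugular", "vein", "catheter", "tip", "projects",
      "superior", "vena", "cava", "heart", "mediastinum",
      "unremarkable", "lungs", "well", "expanded", "bilaterally",
      "diaphragm", "smoothly", "outlined", "bony", "intact",
      "unchanged", "compared", "prior", "signs", "congestion", "soft",
      "tissues")
  }
}

#' Canonicalize institutional abbreviations
#'
#' Maps abbreviated mention tokens back to their canonical form ("pneu",
#' "ptx" -> "pneumothorax") so that n-gram features pool across surface
#' variants instead of fragmenting into rare terms that frequency pruning
#' would delete. This mirrors the role of the curated phrase resources in
#' the detection workflow: the abbreviation inventory is institution
#' knowledge available to preprocessing, while misspellings stay
#' uncorrected (they are the noise channel).
#'
#' @param tokens Character vector of normalized tokens.
#' @param abbreviation_map Named list, canonical word -> character vector
#'   of abbreviated variants (as in [lexicon_config()]).
#' @return Tokens with variants replaced by their canonical form.
#' @export
canonicalize_tokens <- function(tokens, abbreviation_map) {
  if (length(tokens) == 0L || length(abbreviation_map) == 0L) return(tokens)
  lookup <- unlist(lapply(names(abbreviation_map), function(canon) {
    stats::setNames(rep(canon, length(abbreviation_map[[canon]])),
                    abbreviation_map[[canon]])
  }))
  hit <- tokens %in% names(lookup)
  tokens[hit] <- lookup[tokens[hit]]
  tokens
}

pattern_categories <- c("affirmative_pneumothorax", "negated_pneumothorax",
                        "contraindication")

#' Build a pattern library
#'
#' A categorized set of regular expressions for affirmative pneumothorax
#' mentions, negated mentions and contraindication phrases, plus the
#' custom stopword list. Every expression is compiled at construction
#' time; an invalid expression is a configuration error here, never at
#' match time.
#'
#' @param patterns Data frame with columns `category` (one of
#'   `"affirmative_pneumothorax"`, `"negated_pneumothorax"`,
#'   `"contraindication"`), `pattern` (Perl-compatible regex, matched
#'   case-insensitively) and `label`.
#' @param stopwords Character vector of lowercase stopwords.
#' @return Object of class `pattern_library`.
#' @export
pattern_library <- function(patterns, stopwords = character()) {
  patterns <- tibble::as_tibble(patterns)
  stopifnot(all(c("category", "pattern", "label") %in% names(patterns)))
  bad <- setdiff(unique(patterns$category), pattern_categories)
  if (length(bad) > 0) {
    stop_invalid("unknown pattern categories: %s", paste(bad, collapse = ", "))
  }
  for (i in seq_len(nrow(patterns))) {
    ok <- tryCatch({ grepl(patterns$pattern[i], "", perl = TRUE); TRUE },
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) {
      stop_invalid("pattern %d (%s) does not compile: %s",
                   i, patterns$label[i], patterns$pattern[i])
    }
  }
  structure(list(patterns = patterns, stopwords = stopwords),
            class = "pattern_library")
}

# Turn a phrase template into a regex over normalized text: normalize the
# literal parts, escape them, and substitute the mention alternation for
# the {m} slot. Normalized text is single-space separated, so literal
# spaces are safe separators.
template_to_regex <- function(template, mention_alt) {
  parts <- strsplit(template, "{m}", fixed = TRUE)[[1]]
  if (!grepl("{m}", template, fixed = TRUE)) {
    toks <- normalize_text(template)
    return(paste0("\\b", paste(escape_regex(toks), collapse = " "), "\\b"))
  }
  norm_parts <- vapply(parts, function(p) {
    toks <- normalize_text(p)
    if (length(toks) == 0) "" else paste(escape_regex(toks), collapse = " ")
  }, character(1))
  mid <- paste0("(", mention_alt, ")")
  body <- norm_parts[1]
  for (i in seq_along(norm_parts)[-1]) {
    sep1 <- if (nzchar(body)) " " else ""
    sep2 <- if (nzchar(norm_parts[i])) " " else ""
    body <- paste0(body, sep1, mid, sep2, norm_parts[i])
  }
  if (length(norm_parts) < length(parts) + 1 && grepl("\\{m\\}$", template)) {
    # template ends with the slot
    sep1 <- if (nzchar(body)) " " else ""
    body <- paste0(body, sep1, mid)
  }
  paste0("\\b", body, "\\b")
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Derive a pattern library from a lexicon
#'
#' Builds regexes that exactly cover the phrases a [lexicon_config()] can
#' emit: one affirmative pattern matching any mention lexeme (canonical or
#' abbreviated), one negated pattern per negation template, and one
#' contraindication pattern per contraindication phrase. Patterns are
#' written against normalized text (see [normalize_text()]).
#'
#' @param lexicon A [lexicon_config()] object.
#' @return A [pattern_library()].
#' @export
pattern_library_from_lexicon <- function(lexicon) {
  stopifnot(inherits(lexicon, "lexicon_config"))
  mention_alt <- paste(escape_regex(lexicon$mention_lexemes), collapse = "|")
  rows <- list(tibble::tibble(
    category = "affirmative_pneumothorax",
    pattern = paste0("\\b(", mention_alt, ")\\b"),
    label = "pneumothorax mention"))
  for (tmpl in lexicon$negation_templates) {
    rows <- c(rows, list(tibble::tibble(
      category = "negated_pneumothorax",
      pattern = template_to_regex(tmpl, mention_alt),
      label = paste("negated:", tmpl))))
  }
  for (ph in lexicon$contraindication_phrases) {
    rows <- c(rows, list(tibble::tibble(
      category = "contraindication",
      pattern = template_to_regex(ph, mention_alt),
      label = paste("contraindication:", ph))))
  }
  pattern_library(do.call(rbind, rows),
                  stopwords = default_stopwords(lexicon$language))
}

#' Read a pattern library from YAML
#'
#' The file is a YAML list of `{category, pattern, label}` entries;
#' stopwords come from a plain-text file, one token per line.
#'
#' @param path YAML file of patterns.
#' @param stopwords_path Optional stopword file.
#' @return A [pattern_library()].
#' @export
read_pattern_library <- function(path, stopwords_path = NULL) {
  entries <- yaml::read_yaml(path)
  patterns <- do.call(rbind, lapply(entries, function(e) {
    tibble::tibble(category = e$category, pattern = e$pattern, label = e$label)
  }))
  sw <- if (!is.null(stopwords_path)) read_stopwords(stopwords_path) else character()
  pattern_library(patterns, sw)
}

#' @rdname read_pattern_library
#' @export
read_stopwords <- function(path) {
  sw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  sw <- trimws(sw)
  sw[nzchar(sw) & !startsWith(sw, "#")]
}

#' Match categorized patterns in a text
#'
#' Finds all maximal, non-overlapping matches of the library's patterns
#' (case-insensitive, Perl regexes) and reports their character spans.
#' On overlapping spans, negated mentions take precedence over
#' contraindication matches, which take precedence over affirmative
#' mentions — so "kein pneumothorax" yields a single negated match and
#' "vorbekannter pneumothorax" a single contraindication match, never a
#' spurious affirmative hit.
#'
#' @param text Character scalar. For library patterns derived from a
#'   lexicon, pass normalized text, e.g.
#'   `paste(normalize_text(x), collapse = " ")`.
#' @param library A [pattern_library()].
#' @return Tibble with columns `category`, `start`, `end`, `label`,
#'   `match`, ordered by `start`.
#' @export
match_patterns <- function(text, library) {
  stopifnot(inherits(library, "pattern_library"), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(tibble::tibble(category = character(0), start = integer(0),
                          end = integer(0), label = character(0),
                          match = character(0)))
  }
  pats <- library$patterns
  cand <- list()
  for (i in seq_len(nrow(pats))) {
    m <- gregexpr(pats$pattern[i], text, perl = TRUE, ignore.case = TRUE)[[1]]
    if (m[1] == -1L) next
    len <- attr(m, "match.length")
    cand[[length(cand) + 1L]] <- tibble::tibble(
      category = pats$category[i],
      start = as.integer(m),
      end = as.integer(m) + len - 1L,
      label = pats$label[i],
      match = substring(text, m, m + len - 1L))
  }
  if (length(cand) == 0L) {
    return(tibble::tibble(category = character(0), start = integer(0),
                          end = integer(0), label = character(0),
                          match = character(0)))
  }
  all_m <- do.call(rbind, cand)
  prio <- c(negated_pneumothorax = 3L, contraindication = 2L,
            affirmative_pneumothorax = 1L)
  ord <- order(-prio[all_m$category], -(all_m$end - all_m$start),
               all_m$start)
  all_m <- all_m[ord, ]
  kept <- logical(nrow(all_m))
  for (i in seq_len(nrow(all_m))) {
    overlap <- kept & (all_m$start <= all_m$end[i]) & (all_m$end >= all_m$start[i])
    if (!any(overlap)) kept[i] <- TRUE
  }
  out <- all_m[kept, ]
  out[order(out$start), ]
}

#' Rule-based pneumothorax classification
#'
#' The deterministic rule layer: a record is positive iff its normalized
#' report (and optionally request) text contains at least one affirmative
#' pneumothorax mention that is not covered by a negated or
#' contraindication span. On noise-free corpora this recovers the
#' generator labels exactly.
#'
#' @param report_text,request_text Character scalars (`request_text`
#'   optional).
#' @param library A [pattern_library()].
#' @return Logical scalar.
#' @export
classify_rules <- function(report_text, request_text = NULL, library) {
  toks <- normalize_text(report_text)
  if (!is.null(request_text)) toks <- c(toks, normalize_text(request_text))
  text <- paste(toks, collapse = " ")
  m <- match_patterns(text, library)
  any(m$category == "affirmative_pneumothorax")
}

exclusion_reasons <- c("missing_data", "under_18", "outside_12h",
                       "incorrect_placement", "follow_up")

#' Apply the study inclusion/exclusion rules
#'
#' Checks each record against the fixed rule order `missing_data`,
#' `under_18`, `outside_12h`, `incorrect_placement`, `follow_up` and
#' reports the first failing rule. Boundaries are inclusive: age exactly
#' 18 and an X-ray exactly 12.0 hours after the procedure are both
#' included ("aged 18 or older", "within 12 h").
#'
#' @param records Record tibble (one or more rows); fields may be missing
#'   or `NA`.
#' @param max_hours Inclusion window in hours (default 12).
#' @param min_age Minimum age in years (default 18).
#' @return Tibble with one row per record: `included` (logical) and
#'   `reason` (`NA` when included).
#' @export
apply_exclusions <- function(records, max_hours = 12, min_age = 18) {
  n <- nrow(records)
  get <- function(fld, default) {
    if (fld %in% names(records)) records[[fld]] else rep(default, n)
  }
  report <- get("report_text", NA_character_)
  request <- get("request_text", NA_character_)
  age <- get("age_years", NA_integer_)
  hours <- get("hours_since_procedure", NA_real_)
  gender <- get("gender", NA_character_)
  proc <- get("procedure", NA_character_)
  wrong <- get("incorrect_placement", FALSE)
  fup <- get("follow_up", FALSE)

  missing <- is.na(report) | !nzchar(ifelse(is.na(report), "", report)) |
    is.na(request) | is.na(age) | is.na(hours) | is.na(gender) | is.na(proc)
  reason <- rep(NA_character_, n)
  reason[is.na(reason) & missing] <- "missing_data"
  reason[is.na(reason) & age < min_age] <- "under_18"
  reason[is.na(reason) & hours > max_hours] <- "outside_12h"
  reason[is.na(reason) & isTRUE_vec(wrong)] <- "incorrect_placement"
  reason[is.na(reason) & isTRUE_vec(fup)] <- "follow_up"
  tibble::tibble(included = is.na(reason), reason = reason)
}

isTRUE_vec <- function(x) !is.na(x) & x
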