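#' Report lexicon configuration
#'
#' Describes the lexical machinery used to render synthetic radiology
#' reports: affirmative pneumothorax phrases, negation templates (with a
#' `{m}` slot for the mention lexeme), contraindication phrases, an
#' abbreviation map (canonical word to institutional short forms), a
#' misspelling channel, and neutral filler sentences. Two defaults ship:
#' a German-flavoured lexicon (`language = "de"`, the default, mimicking
#' German-language institutional reporting shorthand such as "pneu", "ptx",
#' "z.n.") and an English one (`language = "en"`). Real institutional
#' phrase lists are not public; these lexicons are synthetic stand-ins
#' with the same structural phenomena.
#'
#' @param language `"de"` or `"en"`; selects the default phrase sets.
#' @param misspelling_rate Probability that a rendered phrase receives one
#'   character-level typo (adjacent swap, deletion, or doubling).
#' @param negation_distractor_rate Probability that a pneumothorax-negative
#'   report contains an explicitly negated mention ("kein pneumothorax").
#' @param contraindication_rate Probability that a report carries a
#'   contraindication phrase (chest trauma, prior pneumothorax, recent
#'   thoracic surgery); flagged in the record metadata.
#' @param abbreviation_rate Probability that a canonical mention word is
#'   replaced by one of its abbreviations when rendering a phrase.
#' @param include_size_sentence If `TRUE` (default), positive reports also
#'   state the pneumothorax rim size in mm, as real reports do; set to
#'   `FALSE` for deliberately weak-signal corpora.
#' @param affirmative_phrases,negation_templates,contraindication_phrases,
#'   abbreviation_map,filler_sentence_pool,size_templates,request_templates
#'   Optional overrides of the language defaults.
#' @param seed Integer seed used by [generate_corpus()].
#' @return A validated list of class `lexicon_config`. The derived field
#'   `mention_lexemes` lists every surface form of the pneumothorax mention
#'   (canonical plus abbreviations).
#' @export
lexicon_config <- function(language = c("de", "en"),
                           misspelling_rate = 0,
                           negation_distractor_rate = 0.3,
                           contraindication_rate = 0.05,
                           abbreviation_rate = 0.3,
                           include_size_sentence = TRUE,
                           affirmative_phrases = NULL,
                           negation_templates = NULL,
                           contraindication_phrases = NULL,
                           abbreviation_map = NULL,
                           filler_sentence_pool = NULL,
                           size_templates = NULL,
                           request_templates = NULL,
                           seed = 1L) {
  language <- match.arg(language)
  def <- default_lexicon_phrases(language)
  lex <- list(
    language = language,
    affirmative_phrases = affirmative_phrases %||% def$affirmative_phrases,
    negation_templates = negation_templates %||% def$negation_templates,
    contraindication_phrases = contraindication_phrases %||% def$contraindication_phrases,
    abbreviation_map = abbreviation_map %||% def$abbreviation_map,
    filler_sentence_pool = filler_sentence_pool %||% def$filler_sentence_pool,
    size_templates = size_templates %||% def$size_templates,
    request_templates = request_templates %||% def$request_templates,
    misspelling_rate = misspelling_rate,
    negation_distractor_rate = negation_distractor_rate,
    contraindication_rate = contraindication_rate,
    abbreviation_rate = abbreviation_rate,
    include_size_sentence = isTRUE(include_size_sentence),
    seed = as.integer(seed)
  )
  for (r in c("misspelling_rate", "negation_distractor_rate",
              "contraindication_rate", "abbreviation_rate")) {
    if (!is_prop(lex[[r]])) stop_invalid("%s must lie in [0,1]", r)
  }
  for (fld in c("affirmative_phrases", "negation_templates",
                "contraindication_phrases", "filler_sentence_pool")) {
    if (length(lex[[fld]]) == 0L || !is.character(lex[[fld]])) {
      stop_invalid("invalid lexicon: %s must be a non-empty character vector", fld)
    }
  }
  lex$mention_lexemes <- unique(c(names(lex$abbreviation_map),
                                  unlist(lex$abbreviation_map, use.names = FALSE)))
  structure(lex, class = "lexicon_config")
}

default_lexicon_phrases <- function(language) {
  if (language == "de") {
    list(
      affirmative_phrases = c(
        "pneumothorax rechts apikal",
        "pneumothorax links apikal",
        "schmaler pneumothorax apikal",
        "neu aufgetretener pneumothorax",
        "pneumothorax basal rechts"),
      negation_templates = c(
        "kein {m}",
        "kein nachweis eines {m}",
        "keine hinweise auf {m}",
        "kein anhalt fuer {m}",
        "{m} nicht nachweisbar",
        "ausschluss {m}"),
      contraindication_phrases = c(
        "z.n. thorakotomie",
        "thoraxtrauma nach sturz",
        "vorbekannter pneumothorax",
        "z.n. thoraxchirurgischem eingriff",
        "rippenserienfraktur links"),
      abbreviation_map = list(pneumothorax = c("pneu", "ptx")),
      filler_sentence_pool = c(
        "zvk einlage ueber die vena jugularis interna rechts",
        "katheterspitze in projektion auf die vena cava superior",
        "herz und mediastinum regelrecht",
        "lunge beidseits ausreichend beluftet",
        "kein pleuraerguss",
        "zwerchfellkuppen glatt begrenzt",
        "knoecherner thorax intakt",
        "im vergleich zur voraufnahme unveraendert",
        "keine stauungszeichen",
        "weichteile unauffaellig"),
      size_templates = c(
        "apikaler saum von {size} mm",
        "saum ca {size} mm messend"),
      request_templates = list(
        insertion = c("zvk neuanlage, bitte lagekontrolle",
                      "kontrolle nach zvk anlage, ausschluss {m}"),
        removal = c("zustand nach zvk entfernung, bitte kontrolle",
                    "kontrolle nach zvk zug, ausschluss {m}"))
    )
  } else {
    list(
      affirmative_phrases = c(
        "small apical pneumothorax on the right",
        "pneumothorax in the left apex",
        "new pneumothorax at the right apex",
        "trace basal pneumothorax on the right"),
      negation_templates = c(
        "no {m}",
        "no evidence of {m}",
        "without evidence of {m}",
        "{m} is not seen",
        "rule out {m}"),
      contraindication_phrases = c(
        "status post thoracotomy",
        "known prior pneumothorax",
        "rib fractures after chest trauma",
        "recent thoracic surgery"),
      abbreviation_map = list(pneumothorax = "ptx"),
      filler_sentence_pool = c(
        "central line placed via the right internal jugular vein",
        "catheter tip projects over the superior vena cava",
        "heart and mediastinum unremarkable",
        "lungs well expanded bilaterally",
        "no pleural effusion",
        "diaphragm smoothly outlined",
        "bony thorax intact",
        "unchanged compared with the prior study",
        "no signs of congestion",
        "soft tissues unremarkable"),
      size_templates = c(
        "measuring {size} mm apically",
        "with a {size} mm rim"),
      request_templates = list(
        insertion = c("new central line, please check position",
                      "post line placement, rule out {m}"),
        removal = c("status post central line removal, please check",
                    "after line removal, rule out {m}"))
    )
  }
}

# One character-level typo in a random word of >= 4 characters:
# adjacent swap, deletion, or doubling at a random interior position.
misspell_phrase <- function(phrase) {
  words <- strsplit(phrase, " ", fixed = TRUE)[[1]]
  cand <- which(nchar(words) >= 4)
  if (length(cand) == 0L) return(phrase)
  wi <- cand[sample.int(length(cand), 1L)]
  w <- strsplit(words[wi], "")[[1]]
  pos <- sample(2:(length(w) - 1), 1L)
  op <- sample(c("swap", "drop", "double"), 1L)
  w <- switch(op,
    swap = { tmp <- w[pos]; w[pos] <- w[pos + 1]; w[pos + 1] <- tmp; w },
    drop = w[-pos],
    double = append(w, w[pos], after = pos))
  words[wi] <- paste(w, collapse = "")
  paste(words, collapse = " ")
}

render_mention_word <- function(lexicon) {
  canon <- names(lexicon$abbreviation_map)
  if (length(canon) == 0L) return("pneumothorax")
  word <- canon[1]
  if (runif(1) < lexicon$abbreviation_rate) {
    vars <- lexicon$abbreviation_map[[word]]
    if (length(vars) > 0) word <- sample(vars, 1L)
  }
  word
}

# Replace canonical words by abbreviations inside a phrase, at the
# configured abbreviation rate (per canonical word occurrence).
apply_abbreviations <- function(phrase, lexicon) {
  for (canon in names(lexicon$abbreviation_map)) {
    if (grepl(canon, phrase, fixed = TRUE) &&
        runif(1) < lexicon$abbreviation_rate) {
      abbr <- sample(lexicon$abbreviation_map[[canon]], 1L)
      phrase <- sub(canon, abbr, phrase, fixed = TRUE)
    }
  }
  phrase
}

maybe_misspell <- function(phrase, lexicon) {
  if (runif(1) < lexicon$misspelling_rate) misspell_phrase(phrase) else phrase
}

# Core text renderer shared by generate_report() and generate_corpus().
# Consumes the current RNG state.
render_texts <- function(label, size_mm, procedure, lexicon) {
  n_fill <- sample(2:4, 1L)
  fillers <- sample(lexicon$filler_sentence_pool, n_fill)
  inserts <- character(0)

  if (isTRUE(label)) {
    n_m <- 1L + stats::rbinom(1L, 1L, 0.5)
    tmpl <- sample(lexicon$affirmative_phrases, n_m,
                   replace = n_m > length(lexicon$affirmative_phrases))
    for (ph in tmpl) {
      ph <- apply_abbreviations(ph, lexicon)
      inserts <- c(inserts, maybe_misspell(ph, lexicon))
    }
    if (lexicon$include_size_sentence && !is.na(size_mm)) {
      st <- sample(lexicon$size_templates, 1L)
      st <- gsub("{size}", as.character(round(size_mm)), st, fixed = TRUE)
      inserts <- c(inserts, maybe_misspell(st, lexicon))
    }
  } else if (runif(1) < lexicon$negation_distractor_rate) {
    tmpl <- sample(lexicon$negation_templates, 1L)
    ph <- gsub("{m}", render_mention_word(lexicon), tmpl, fixed = TRUE)
    inserts <- c(inserts, maybe_misspell(ph, lexicon))
  }

  contra <- runif(1) < lexicon$contraindication_rate
  if (contra) inserts <- c(inserts, sample(lexicon$contraindication_phrases, 1L))

  sentences <- fillers
  for (s in inserts) {
    pos <- sample.int(length(sentences) + 1L, 1L) - 1L
    sentences <- append(sentences, s, after = pos)
  }

  rt <- lexicon$request_templates[[procedure]] %||%
    lexicon$request_templates[["insertion"]]
  req <- sample(rt, 1L)
  req <- gsub("{m}", names(lexicon$abbreviation_map)[1] %||% "pneumothorax",
              req, fixed = TRUE)

  list(report_text = paste0(paste(sentences, collapse = ". "), "."),
       request_text = req,
       contraindication_present = contra)
}

#' Fill in report and request text for one record
#'
#' Renders the free text implied by the record's metadata. A positive
#' record receives one or two affirmative pneumothorax mentions (possibly
#' abbreviated and/or misspelled) and, unless disabled, a rim-size sentence
#' derived from `pneumothorax_size_mm`. A negative record receives no
#' affirmative mention, but with probability `negation_distractor_rate` a
#' negated mention is inserted. Contraindication phrases are injected at
#' `contraindication_rate` and flagged in `contraindication_present`.
#' Filler sentences are neutral and never mention pneumothorax
#' affirmatively.
#'
#' Uses the current RNG state; [generate_corpus()] seeds it once from
#' `lexicon$seed` for whole-corpus reproducibility.
#'
#' @param record A one-row tibble as produced by [generate_cohort()].
#' @param lexicon A [lexicon_config()] object.
#' @return The record with `report_text`, `request_text` and
#'   `contraindication_present` filled in.
#' @export
generate_report <- function(record, lexicon) {
  stopifnot(inherits(lexicon, "lexicon_config"))
  tx <- render_texts(record$label_pneumothorax, record$pneumothorax_size_mm,
                     record$procedure, lexicon)
  record$report_text <- tx$report_text
  record$request_text <- tx$request_text
  record$contraindication_present <- tx$contraindication_present
  record
}

#' Fill in texts for a whole cohort
#'
#' Applies the renderer of [generate_report()] to every record under a
#' single seed taken from `lexicon$seed`, so identical inputs give a
#' byte-identical corpus.
#'
#' @param records Tibble from [generate_cohort()].
#' @param lexicon A [lexicon_config()] object.
#' @return The records with texts and contraindication flags filled.
#' @export
generate_corpus <- function(records, lexicon) {
  stopifnot(inherits(lexicon, "lexicon_config"))
  n <- nrow(records)
  label <- records$label_pneumothorax
  size <- records$pneumothorax_size_mm
  proc <- records$procedure
  rep_txt <- character(n); req_txt <- character(n); contra <- logical(n)
  withr::with_seed(lexicon$seed, {
    for (i in seq_len(n)) {
      tx <- render_texts(label[i], size[i], proc[i], lexicon)
      rep_txt[i] <- tx$report_text
      req_txt[i] <- tx$request_text
      contra[i] <- tx$contraindication_present
    }
  })
  records$report_text <- rep_txt
  records$request_text <- req_txt
  records$contraindication_present <- contra
  records
}
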