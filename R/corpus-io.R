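record_fields <- c("record_id", "report_text", "request_text", "age_years",
                   "gender", "procedure", "hours_since_procedure",
                   "department", "label_pneumothorax")
optional_fields <- c("pneumothorax_size_mm", "contraindication_present",
                     "incorrect_placement", "follow_up")

#' Write a corpus to a JSON-lines file
#'
#' One UTF-8 JSON object per line, field names exactly as in the record
#' tibble. `pneumothorax_size_mm` is omitted for negative records (it is
#' defined only when the label is positive). Numeric fields keep full
#' precision so that `read_corpus(write_corpus(x))` round-trips.
#'
#' @param records Record tibble (see [generate_cohort()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(records, path) {
  lines <- vapply(seq_len(nrow(records)), function(i) {
    rec <- as.list(records[i, ])
    if (is.na(rec$pneumothorax_size_mm)) rec$pneumothorax_size_mm <- NULL
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a corpus from a JSON-lines file
#'
#' Validates that every mandatory field is present; a malformed line or a
#' missing field raises an error naming the line number (and field).
#'
#' @param path JSONL file written by [write_corpus()] (or compatible).
#' @return A record tibble.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_corpus())
  rows <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e) {
                      stop_invalid("parse error on line %d: %s", i, conditionMessage(e))
                    })
    missing <- setdiff(record_fields, names(rec))
    if (length(missing) > 0) {
      stop_invalid("line %d: missing mandatory field(s): %s",
                   i, paste(missing, collapse = ", "))
    }
    rec$pneumothorax_size_mm <- rec$pneumothorax_size_mm %||% NA_real_
    rec$contraindication_present <- rec$contraindication_present %||% FALSE
    rec$incorrect_placement <- rec$incorrect_placement %||% FALSE
    rec$follow_up <- rec$follow_up %||% FALSE
    tibble::as_tibble(rec[c(record_fields, optional_fields)])
  })
  out <- do.call(rbind, rows)
  out$age_years <- as.integer(out$age_years)
  out
}

empty_corpus <- function() {
  tibble::tibble(
    record_id = character(0), report_text = character(0),
    request_text = character(0), age_years = integer(0),
    gender = character(0), procedure = character(0),
    hours_since_procedure = numeric(0), department = character(0),
    label_pneumothorax = logical(0), pneumothorax_size_mm = numeric(0),
    contraindication_present = logical(0), incorrect_placement = logical(0),
    follow_up = logical(0))
}

#' Write a corpus as CSV
#'
#' Companion flat export with the same columns as the JSONL format.
#'
#' @param records Record tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_corpus_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
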