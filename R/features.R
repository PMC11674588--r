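#' N-gram tokenization
#'
#' Forms the `length(tokens) - n + 1` consecutive n-grams of a token
#' sequence, joined with `"_"`. Documents shorter than `n` tokens yield an
#' empty result.
#'
#' @param tokens Character vector of tokens (see [normalize_text()]).
#' @param n N-gram order (2 = bi-grams, the default feature unit).
#' @return Character vector of n-grams, in order.
#' @export
tokenize_ngrams <- function(tokens, n = 2L) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 ||
      n != floor(n)) {
    stop_invalid("n-gram order must be a positive integer")
  }
  n <- as.integer(n)
  len <- length(tokens)
  if (len < n) return(character(0))
  if (n == 1L) return(tokens)
  out <- tokens[seq_len(len - n + 1L)]
  for (k in seq_len(n - 1L)) {
    out <- paste(out, tokens[(1L + k):(len - n + 1L + k)], sep = "_")
  }
  out
}

#' Build a document-term matrix of n-gram counts
#'
#' The vocabulary is the lexicographically sorted union of observed
#' n-grams; `counts[d, t]` is the number of occurrences of term `t` in
#' document `d` (sparse). `doc_frequency[t]` counts the documents
#' containing `t` at least once.
#'
#' @param token_lists List of token vectors, one per document.
#' @param n N-gram order.
#' @param doc_ids Optional document identifiers (defaults to names or
#'   running index).
#' @return Object of class `pneumo_dtm`: list with `counts`
#'   (a [Matrix::sparseMatrix()], docs x terms), `vocabulary`,
#'   `n_documents`, `ngram_order`, `doc_frequency`.
#' @export
build_dtm <- function(token_lists, n = 2L, doc_ids = NULL) {
  if (length(token_lists) == 0L) stop_invalid("corpus is empty")
  doc_ids <- doc_ids %||% names(token_lists) %||%
    sprintf("doc%06d", seq_along(token_lists))
  grams <- lapply(token_lists, tokenize_ngrams, n = n)
  vocab <- sort(unique(unlist(grams, use.names = FALSE)))
  counts <- ngram_counts(grams, vocab, doc_ids)
  new_dtm(counts, vocab, as.integer(n))
}

ngram_counts <- function(grams, vocab, doc_ids) {
  di <- rep(seq_along(grams), lengths(grams))
  term <- unlist(grams, use.names = FALSE)
  keep <- term %in% vocab
  ji <- match(term[keep], vocab)
  Matrix::sparseMatrix(i = di[keep], j = ji, x = 1,
                       dims = c(length(grams), length(vocab)),
                       dimnames = list(doc_ids, vocab))
}

new_dtm <- function(counts, vocab, n) {
  structure(list(
    counts = counts,
    vocabulary = vocab,
    n_documents = nrow(counts),
    ngram_order = n,
    doc_frequency = Matrix::colSums(counts > 0)
  ), class = "pneumo_dtm")
}

#' @export
print.pneumo_dtm <- function(x, ...) {
  cat(sprintf("<pneumo_dtm> %d documents x %d %d-gram terms (%.2f%% filled)\n",
              x$n_documents, length(x$vocabulary), x$ngram_order,
              100 * Matrix::nnzero(x$counts) /
                max(1, prod(dim(x$counts)))))
  invisible(x)
}

#' Prune rare terms from a document-term matrix
#'
#' Removes every term whose frequency statistic is at most
#' `fraction * N`, where `N` is the number of documents — i.e. it keeps
#' exactly the terms with statistic strictly greater than the threshold.
#' The statistic is the document frequency by default (`mode =
#' "doc_freq"`, "appearing in fewer than 1% of cases"); `mode =
#' "total_count"` uses total occurrence counts instead. Column order is
#' preserved and `N` is unchanged.
#'
#' @param dtm A `pneumo_dtm`.
#' @param fraction Pruning fraction in \[0, 1); default 0.01.
#' @param mode `"doc_freq"` or `"total_count"`.
#' @return The pruned `pneumo_dtm`.
#' @export
prune_features <- function(dtm, fraction = 0.01,
                           mode = c("doc_freq", "total_count")) {
  stopifnot(inherits(dtm, "pneumo_dtm"))
  mode <- match.arg(mode)
  if (!is.numeric(fraction) || fraction < 0 || fraction >= 1) {
    stop_invalid("fraction must lie in [0, 1)")
  }
  stat <- switch(mode,
                 doc_freq = dtm$doc_frequency,
                 total_count = Matrix::colSums(dtm$counts))
  keep <- stat > fraction * dtm$n_documents
  if (!any(keep)) {
    stop_invalid(paste("pruning at fraction %.3f removed every term;",
                       "downstream training is impossible"), fraction)
  }
  new_dtm(dtm$counts[, keep, drop = FALSE], dtm$vocabulary[keep],
          dtm$ngram_order)
}

#' Project documents onto a fixed vocabulary
#'
#' Counts n-grams of new documents against a previously fitted
#' vocabulary; terms absent from a document give zero columns, and
#' out-of-vocabulary n-grams are dropped. This is the leakage-free way to
#' transform a test split with a training-split vocabulary.
#'
#' @param token_lists List of token vectors.
#' @param vocabulary Character vector (training vocabulary).
#' @param n N-gram order used at fit time.
#' @param doc_ids Optional document ids.
#' @return A `pneumo_dtm` over `vocabulary`.
#' @export
project_dtm <- function(token_lists, vocabulary, n = 2L, doc_ids = NULL) {
  if (length(token_lists) == 0L) stop_invalid("corpus is empty")
  doc_ids <- doc_ids %||% names(token_lists) %||%
    sprintf("doc%06d", seq_along(token_lists))
  grams <- lapply(token_lists, tokenize_ngrams, n = n)
  counts <- ngram_counts(grams, vocabulary, doc_ids)
  new_dtm(counts, vocabulary, as.integer(n))
}

#' Export / import a document-term matrix
#'
#' Writes the sparse counts as a MatrixMarket file plus plain-text
#' vocabulary and document-id files and a small JSON metadata file; the
#' round trip is bit-exact for integer counts.
#'
#' @param dtm A `pneumo_dtm`.
#' @param stem Path stem; files `<stem>.mtx`, `<stem>.vocab.txt`,
#'   `<stem>.docs.txt`, `<stem>.meta.json` are written.
#' @return `stem`, invisibly (`write_dtm`); a `pneumo_dtm` (`read_dtm`).
#' @export
write_dtm <- function(dtm, stem) {
  stopifnot(inherits(dtm, "pneumo_dtm"))
  Matrix::writeMM(dtm$counts, paste0(stem, ".mtx"))
  writeLines(dtm$vocabulary, paste0(stem, ".vocab.txt"), useBytes = TRUE)
  writeLines(rownames(dtm$counts), paste0(stem, ".docs.txt"), useBytes = TRUE)
  jsonlite::write_json(list(ngram_order = dtm$ngram_order,
                            n_documents = dtm$n_documents),
                       paste0(stem, ".meta.json"), auto_unbox = TRUE)
  invisible(stem)
}

#' @rdname write_dtm
#' @export
read_dtm <- function(stem) {
  counts <- methods::as(Matrix::readMM(paste0(stem, ".mtx")), "CsparseMatrix")
  vocab <- readLines(paste0(stem, ".vocab.txt"), encoding = "UTF-8")
  docs <- readLines(paste0(stem, ".docs.txt"), encoding = "UTF-8")
  meta <- jsonlite::read_json(paste0(stem, ".meta.json"))
  dimnames(counts) <- list(docs, vocab)
  new_dtm(counts, vocab, as.integer(meta$ngram_order))
}
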