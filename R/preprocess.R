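#' Tokenize a single note
#'
#' Splits on whitespace (spaces, tabs, newlines, carriage returns), converts
#' to lower case, deletes nonalphabetic characters inside each token, and
#' drops tokens of length <= 1. Order and duplicates are preserved; the
#' function is total on strings (empty input gives an empty token vector).
#'
#' @param text A character scalar.
#' @param ascii_only If `TRUE` (default) "alphabetic" means ASCII `a-z`
#'   after lowercasing; if `FALSE`, any Unicode letter is kept.
#' @return Character vector of tokens.
#' @export
tokenize_note <- function(text, ascii_only = TRUE) {
  if (length(text) != 1L || is.na(text)) {
    stop("`text` must be a single non-NA string", call. = FALSE)
  }
  toks <- strsplit(text, "[ \t\r\n]+")[[1]]
  toks <- tolower(toks)
  pattern <- if (ascii_only) "[^a-z]" else "[^[:alpha:]]"
  toks <- gsub(pattern, "", toks)
  toks[nchar(toks) >= 2L]
}

#' Tokenize a raw corpus
#'
#' Applies [tokenize_note()] to every record of a raw corpus, keeping the
#' note-level metadata (document, patient, quarter) aligned with the token
#' sequences.
#'
#' @param corpus A `raw_corpus` data frame (columns `doc_id`, `patient_id`,
#'   `quarter`, `text`), e.g. from [generate_corpus()] or
#'   [read_corpus_jsonl()].
#' @inheritParams tokenize_note
#' @return A `tokenized_corpus`: data frame with columns `doc_id`,
#'   `patient_id`, `quarter` and a list-column `tokens`.
#' @export
tokenize_corpus <- function(corpus, ascii_only = TRUE) {
  stopifnot(is.data.frame(corpus))
  need <- c("doc_id", "patient_id", "quarter", "text")
  if (!all(need %in% names(corpus))) {
    stop("`corpus` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  toks <- lapply(corpus$text, tokenize_note, ascii_only = ascii_only)
  out <- data.frame(doc_id = corpus$doc_id,
                    patient_id = corpus$patient_id,
                    quarter = as.integer(corpus$quarter),
                    stringsAsFactors = FALSE)
  out$tokens <- toks
  class(out) <- c("tokenized_corpus", "data.frame")
  out
}

#' Map calendar dates to chronological quarter indices
#'
#' Quarters follow the calendar convention Jan-Mar, Apr-Jun, Jul-Sep,
#' Oct-Dec; the index is 1-based and chronological from the first quarter of
#' `origin_year`, so a five-year study window spans quarters 1..20.
#'
#' @param dates A `Date` vector or ISO-8601 date strings.
#' @param origin_year Calendar year whose first quarter maps to index 1.
#' @return Integer vector of quarter indices.
#' @export
quarter_index <- function(dates, origin_year) {
  d <- as.Date(dates)
  if (anyNA(d)) stop("unparseable dates", call. = FALSE)
  year <- as.integer(format(d, "%Y"))
  month <- as.integer(format(d, "%m"))
  (year - as.integer(origin_year)) * 4L + (month - 1L) %/% 3L + 1L
}

#' Restrict to the closed cohort
#'
#' Keeps exactly the notes of patients who have at least one note in every
#' quarter `1..n_quarters` — the closed-cohort design under which every
#' patient-quarter stratum is populated.
#'
#' @param corpus A `tokenized_corpus`.
#' @param n_quarters Number of quarterly strata that must all be covered.
#' @return The filtered `tokenized_corpus`.
#' @export
filter_closed_cohort <- function(corpus, n_quarters) {
  stopifnot(inherits(corpus, "tokenized_corpus"))
  n_quarters <- assert_count(n_quarters, "n_quarters")
  if (nrow(corpus) == 0L) return(corpus)
  if (any(corpus$quarter < 1L | corpus$quarter > n_quarters)) {
    stop("quarter indices must lie in 1..n_quarters", call. = FALSE)
  }
  covered <- tapply(corpus$quarter, corpus$patient_id,
                    function(q) length(unique(q)))
  keep_pat <- names(covered)[covered == n_quarters]
  out <- corpus[corpus$patient_id %in% keep_pat, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the corpus vocabulary
#'
#' Ranks tokens by decreasing corpus-wide occurrence count (alphabetical
#' within ties, for determinism), drops stoplist members and tokens below
#' `min_count`, and optionally truncates to the `max_size` most frequent.
#' This configurable triple stands in for manual lexicon curation.
#'
#' @param corpus A `tokenized_corpus`.
#' @param min_count Minimum corpus-wide count for inclusion (>= 1).
#' @param stoplist Character vector of tokens to exclude.
#' @param max_size Optional cap on vocabulary size.
#' @return A `vocabulary`: data frame with columns `token`, `count`, ordered
#'   by decreasing count.
#' @export
build_vocabulary <- function(corpus, min_count = 1L,
                             stoplist = character(), max_size = NULL) {
  stopifnot(inherits(corpus, "tokenized_corpus"))
  min_count <- assert_count(min_count, "min_count")
  counts <- table(unlist(corpus$tokens, use.names = FALSE))
  if (length(counts)) {
    counts <- counts[!(names(counts) %in% stoplist)]
    counts <- counts[counts >= min_count]
  }
  if (length(counts) == 0L) {
    stop("empty vocabulary: no token passed the stoplist/min_count filter",
         call. = FALSE)
  }
  ord <- order(-as.integer(counts), names(counts))
  counts <- counts[ord]
  if (!is.null(max_size)) {
    max_size <- assert_count(max_size, "max_size")
    counts <- counts[seq_len(min(max_size, length(counts)))]
  }
  out <- data.frame(token = names(counts),
                    count = as.integer(counts),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("vocabulary", "data.frame")
  out
}

#' Build a sparse document-term matrix
#'
#' Constructs the D x V count matrix at either note level (one row per note)
#' or patient-quarter level (notes of a patient within a quarter pooled; one
#' row for every patient x quarter pair, so the grid is complete even when a
#' stratum contributes no in-vocabulary tokens). Out-of-vocabulary tokens
#' are ignored.
#'
#' @param corpus A `tokenized_corpus`.
#' @param vocab A `vocabulary` from [build_vocabulary()].
#' @param level `"note"` or `"patient_quarter"`.
#' @param n_quarters Number of quarters spanned by the patient-quarter grid;
#'   defaults to the maximum quarter index observed.
#' @return A `dtm`: list with `counts` (a `dgCMatrix`), `row_meta` (data
#'   frame `unit_id`, `patient_id`, `quarter`), `level`, and `vocabulary`.
#' @export
build_dtm <- function(corpus, vocab,
                      level = c("note", "patient_quarter"),
                      n_quarters = NULL) {
  stopifnot(inherits(corpus, "tokenized_corpus"),
            inherits(vocab, "vocabulary"))
  level <- match.arg(level)
  if (nrow(vocab) == 0L) stop("empty vocabulary", call. = FALSE)
  v <- nrow(vocab)

  if (level == "note") {
    row_meta <- data.frame(unit_id = corpus$doc_id,
                           patient_id = corpus$patient_id,
                           quarter = corpus$quarter,
                           stringsAsFactors = FALSE)
    row_of_note <- seq_len(nrow(corpus))
  } else {
    n_quarters <- if (is.null(n_quarters)) {
      if (nrow(corpus)) max(corpus$quarter) else 1L
    } else assert_count(n_quarters, "n_quarters")
    patients <- sort(unique(corpus$patient_id))
    row_meta <- data.frame(
      patient_id = rep(patients, each = n_quarters),
      quarter = rep.int(seq_len(n_quarters), length(patients)),
      stringsAsFactors = FALSE)
    row_meta$unit_id <- paste0(row_meta$patient_id, "_q", row_meta$quarter)
    row_meta <- row_meta[, c("unit_id", "patient_id", "quarter")]
    row_of_note <- match(paste0(corpus$patient_id, "_q", corpus$quarter),
                         row_meta$unit_id)
  }

  lens <- lengths(corpus$tokens)
  all_tokens <- unlist(corpus$tokens, use.names = FALSE)
  col_idx <- match(all_tokens, vocab$token)
  row_idx <- rep(row_of_note, lens)
  keep <- !is.na(col_idx)
  counts <- Matrix::sparseMatrix(
    i = row_idx[keep], j = col_idx[keep], x = 1,
    dims = c(nrow(row_meta), v),
    dimnames = list(row_meta$unit_id, vocab$token))
  counts <- methods::as(counts, "CsparseMatrix")
  structure(
    list(counts = counts, row_meta = row_meta, level = level,
         vocabulary = vocab),
    class = "dtm")
}

#' Descriptive summary of a document-term matrix
#'
#' Reports unit/patient counts, total in-vocabulary token count, sparsity
#' (fraction of zero cells), and the `top_n` most frequent vocabulary terms
#' with their counts and shares of the total token count.
#'
#' @param dtm A `dtm` from [build_dtm()].
#' @param top_n Number of top terms to tabulate (default 25).
#' @return A `corpus_summary` list.
#' @export
summarize_corpus <- function(dtm, top_n = 25L) {
  stopifnot(inherits(dtm, "dtm"))
  top_n <- assert_count(top_n, "top_n")
  x <- dtm$counts
  total <- sum(x)
  term_counts <- Matrix::colSums(x)
  ord <- order(-term_counts, names(term_counts))
  top_n <- min(top_n, length(term_counts))
  top <- data.frame(
    token = names(term_counts)[ord][seq_len(top_n)],
    count = unname(term_counts[ord][seq_len(top_n)]),
    stringsAsFactors = FALSE)
  top$share <- if (total > 0) top$count / total else 0
  structure(
    list(n_units = nrow(x),
         n_patients = length(unique(dtm$row_meta$patient_id)),
         n_tokens_total = total,
         vocab_size = ncol(x),
         sparsity = 1 - Matrix::nnzero(x) / (as.double(nrow(x)) * ncol(x)),
         top_terms = top,
         level = dtm$level),
    class = "corpus_summary")
}

#' @export
print.corpus_summary <- function(x, ...) {
  cat(sprintf(
    "Corpus summary (%s level): %d units, %d patients, %s tokens, V=%d\n",
    x$level, x$n_units, x$n_patients,
    format(x$n_tokens_total, big.mark = ","), x$vocab_size))
  cat(sprintf("DTM sparsity: %.2f%%\n", 100 * x$sparsity))
  cat("Top terms:\n")
  print(utils::head(x$top_terms, 10), row.names = FALSE)
  invisible(x)
}

#' Read and write document-term matrices as plain text
#'
#' The DTM is stored as Matrix Market sparse coordinates (`dtm.mtx`), the
#' vocabulary as a TSV (`vocabulary.tsv`: token, count), and the row
#' metadata as a TSV (`row_meta.tsv`: unit_id, patient_id, quarter).
#'
#' @param dtm A `dtm`.
#' @param dir Directory to write into (created if needed).
#' @return `read_dtm` returns a `dtm`; `write_dtm` returns `dir` invisibly.
#' @export
write_dtm <- function(dtm, dir) {
  stopifnot(inherits(dtm, "dtm"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(dtm$counts, file.path(dir, "dtm.mtx"))
  utils::write.table(dtm$vocabulary, file.path(dir, "vocabulary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dtm$row_meta, file.path(dir, "row_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(dtm$level, file.path(dir, "level.txt"))
  invisible(dir)
}

#' @rdname write_dtm
#' @export
read_dtm <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "dtm.mtx")),
                        "CsparseMatrix")
  vocab <- utils::read.table(file.path(dir, "vocabulary.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE,
                             quote = "", comment.char = "")
  class(vocab) <- c("vocabulary", "data.frame")
  row_meta <- utils::read.table(file.path(dir, "row_meta.tsv"), sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE,
                                quote = "", comment.char = "")
  dimnames(counts) <- list(row_meta$unit_id, vocab$token)
  level <- readLines(file.path(dir, "level.txt"), n = 1L)
  structure(
    list(counts = counts, row_meta = row_meta, level = level,
         vocabulary = vocab),
    class = "dtm")
}
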