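#' Synthetic closed-cohort corpora with planted topics
#'
#' Real clinical note corpora cannot be shared, so validation of the temporal
#' topic-modelling pipeline rests on simulated corpora whose topic-word
#' distributions and per-quarter topical-prevalence curves are known exactly.
#' These generators emulate a closed cohort: a fixed set of patients, each
#' contributing at least one note in every quarterly stratum, with notes drawn
#' as token mixtures over planted topics whose prevalence is either constant
#' over time or seasonal with a configurable period (default 4 quarters, the
#' annual cycle that drives influenza-vaccination and respiratory-disease
#' activity in primary care).
#'
#' @name synthetic_corpus
NULL

#' Cohort design for corpus simulation
#'
#' @param n_patients Number of patients in the closed cohort.
#' @param n_quarters Number of quarterly strata (default 20, five years).
#' @param notes_per_patient_quarter Either a fixed positive integer or a list
#'   `list(type = "one_plus_poisson", mean = m)`: notes per patient-quarter
#'   drawn as `1 + Poisson(m)`, guaranteeing the closed-cohort minimum of one
#'   note per stratum.
#' @param doc_length Either a fixed positive integer or a list
#'   `list(type = "truncated_poisson", mean = m, min = l)`: tokens per note
#'   drawn as `Poisson(m)` left-truncated at `l` (default mean 40, min 5,
#'   echoing short clinical notes while keeping every note nonempty).
#' @param seed Integer seed; simulation is fully reproducible from it.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_patients,
                        n_quarters = 20L,
                        notes_per_patient_quarter = list(
                          type = "one_plus_poisson", mean = 1),
                        doc_length = list(
                          type = "truncated_poisson", mean = 40, min = 5),
                        seed = 1L) {
  n_patients <- assert_count(n_patients, "n_patients")
  n_quarters <- assert_count(n_quarters, "n_quarters")
  notes_per_patient_quarter <- normalize_count_dist(
    notes_per_patient_quarter, "notes_per_patient_quarter", min_allowed = 1L)
  doc_length <- normalize_count_dist(doc_length, "doc_length",
                                     min_allowed = 1L)
  structure(
    list(n_patients = n_patients,
         n_quarters = n_quarters,
         notes_per_patient_quarter = notes_per_patient_quarter,
         doc_length = doc_length,
         seed = as.integer(seed)),
    class = "cohort_spec")
}

normalize_count_dist <- function(x, name, min_allowed = 1L) {
  if (is.numeric(x) && length(x) == 1L) {
    v <- assert_count(x, name, min = min_allowed)
    return(list(type = "fixed", value = v))
  }
  if (is.list(x) && !is.null(x$type)) {
    if (x$type == "fixed") {
      x$value <- assert_count(x$value, paste0(name, "$value"),
                              min = min_allowed)
      return(x[c("type", "value")])
    }
    if (x$type == "one_plus_poisson") {
      if (!is.numeric(x$mean) || x$mean < 0) {
        stop(sprintf("`%s$mean` must be nonnegative", name), call. = FALSE)
      }
      return(list(type = "one_plus_poisson", mean = as.numeric(x$mean)))
    }
    if (x$type == "truncated_poisson") {
      min_v <- assert_count(x$min %||% 1L, paste0(name, "$min"))
      if (!is.numeric(x$mean) || x$mean <= 0) {
        stop(sprintf("`%s$mean` must be positive", name), call. = FALSE)
      }
      return(list(type = "truncated_poisson", mean = as.numeric(x$mean),
                  min = min_v))
    }
  }
  stop(sprintf("unrecognized distribution spec for `%s`", name),
       call. = FALSE)
}

draw_counts <- function(dist, n) {
  switch(dist$type,
    fixed = rep.int(dist$value, n),
    one_plus_poisson = 1L + stats::rpois(n, dist$mean),
    truncated_poisson = {
      x <- stats::rpois(n, dist$mean)
      while (any(x < dist$min)) {
        redo <- x < dist$min
        x[redo] <- stats::rpois(sum(redo), dist$mean)
      }
      x
    },
    stop("unknown distribution type"))
}

#' Deterministic synthetic vocabulary
#'
#' Builds `n` distinct lowercase alphabetic words (length >= 2), so the
#' standard tokenizer is the identity on clean synthetic text.
#'
#' @param n Number of words.
#' @return Character vector of `n` unique words.
#' @export
synthetic_vocabulary <- function(n) {
  n <- assert_count(n, "n")
  width <- max(2L, ceiling(log(n + 1) / log(26)))
  idx <- seq_len(n) - 1L
  chars <- matrix("", nrow = n, ncol = width)
  for (pos in seq_len(width)) {
    chars[, width - pos + 1L] <- letters[(idx %% 26L) + 1L]
    idx <- idx %/% 26L
  }
  apply(chars, 1L, paste0, collapse = "")
}

#' Draw planted topic-word distributions
#'
#' Each topic is a probability distribution over the synthetic vocabulary,
#' drawn from a symmetric Dirichlet. Small concentrations give sparse,
#' well-separated topics (most mass on a few words), mimicking the focused
#' word clusters that topic models extract from clinical text.
#'
#' @param k_true Number of planted topics.
#' @param vocab_size Vocabulary size `V` (must be at least `k_true`).
#' @param concentration Symmetric Dirichlet concentration (> 0).
#' @param seed Integer seed.
#' @return A `k_true` x `vocab_size` row-stochastic matrix; column names are
#'   the synthetic vocabulary, row names `topic_1..topic_K`.
#' @export
make_topics <- function(k_true, vocab_size, concentration, seed = 1L) {
  k_true <- assert_count(k_true, "k_true")
  vocab_size <- assert_count(vocab_size, "vocab_size")
  if (vocab_size < k_true) {
    stop("`vocab_size` must be >= `k_true`", call. = FALSE)
  }
  assert_positive_scalar(concentration, "concentration")
  phi <- with_seed(seed, {
    rdirichlet_rows(k_true, rep(concentration, vocab_size))
  })
  dimnames(phi) <- list(paste0("topic_", seq_len(k_true)),
                        synthetic_vocabulary(vocab_size))
  phi
}

#' Trend specifications for planted prevalence curves
#'
#' `trend_constant()` plants a topic whose expected prevalence does not vary
#' over quarters. `trend_seasonal()` plants an annual-cycle topic: before
#' renormalization its prevalence at quarter `t` (1-based) is
#' `base * (1 + amplitude * cos(2 * pi * ((t - 1) - phase) / period))`,
#' peaking at quarter `1 + phase` and every `period` quarters thereafter.
#'
#' @param amplitude Relative seasonal amplitude, in `[0, 1)`.
#' @param period Period in quarters (default 4, one year).
#' @param phase Phase offset in quarters (default 0: peak in quarter 1).
#' @param base Relative base weight of the topic before renormalization
#'   (default 1: equal weight with other unit-base topics).
#' @return A trend-spec list understood by [make_prevalence_curves()].
#' @export
trend_constant <- function(base = 1) {
  assert_positive_scalar(base, "base")
  list(type = "constant", base = base)
}

#' @rdname trend_constant
#' @export
trend_seasonal <- function(amplitude, period = 4, phase = 0, base = 1) {
  if (!is.numeric(amplitude) || length(amplitude) != 1L ||
      amplitude < 0 || amplitude >= 1) {
    stop("`amplitude` must lie in [0, 1): amplitude >= 1 would produce ",
         "negative prevalence", call. = FALSE)
  }
  assert_positive_scalar(period, "period")
  assert_positive_scalar(base, "base")
  list(type = "seasonal", amplitude = amplitude, period = period,
       phase = phase, base = base)
}

#' Planted per-quarter topical-prevalence curves
#'
#' @param n_quarters Number of quarters `T`.
#' @param trend_specs List of per-topic trend specs ([trend_constant()] or
#'   [trend_seasonal()]), one per planted topic.
#' @return A `T` x `K` matrix; row `t` is the expected topic mixture of
#'   documents generated at quarter `t` and sums to 1.
#' @export
make_prevalence_curves <- function(n_quarters, trend_specs) {
  n_quarters <- assert_count(n_quarters, "n_quarters")
  if (!is.list(trend_specs) || length(trend_specs) == 0L) {
    stop("`trend_specs` must be a nonempty list of trend specs",
         call. = FALSE)
  }
  k <- length(trend_specs)
  t_idx <- seq_len(n_quarters)
  raw <- vapply(trend_specs, function(ts) {
    if (is.null(ts$type)) stop("malformed trend spec", call. = FALSE)
    if (ts$type == "constant") {
      rep(ts$base %||% 1, n_quarters)
    } else if (ts$type == "seasonal") {
      if (ts$amplitude >= 1) {
        stop("seasonal amplitude must be < 1", call. = FALSE)
      }
      base <- ts$base %||% 1
      base * (1 + ts$amplitude *
                cos(2 * pi * ((t_idx - 1) - ts$phase) / ts$period))
    } else {
      stop("unknown trend type: ", ts$type, call. = FALSE)
    }
  }, numeric(n_quarters))
  raw <- matrix(raw, nrow = n_quarters, ncol = k)
  curves <- raw / rowSums(raw)
  dimnames(curves) <- list(paste0("q", t_idx), paste0("topic_", seq_len(k)))
  curves
}

#' Bundle planted ground truth for recovery tests
#'
#' @param phi_true `K x V` row-stochastic topic-word matrix (see
#'   [make_topics()]).
#' @param prevalence_curves `T x K` row-stochastic prevalence matrix (see
#'   [make_prevalence_curves()]).
#' @param trend_specs The per-topic trend specs used to build the curves.
#' @param seed Integer seed recorded for provenance.
#' @return A `synthetic_ground_truth` object.
#' @export
synthetic_ground_truth <- function(phi_true, prevalence_curves,
                                   trend_specs = NULL, seed = NA_integer_) {
  stopifnot(is.matrix(phi_true), is.matrix(prevalence_curves))
  if (ncol(prevalence_curves) != nrow(phi_true)) {
    stop("`prevalence_curves` must have one column per row of `phi_true`",
         call. = FALSE)
  }
  check_row_stochastic(phi_true, "phi_true")
  check_row_stochastic(prevalence_curves, "prevalence_curves")
  structure(
    list(phi_true = phi_true,
         prevalence_curves = prevalence_curves,
         trend_specs = trend_specs,
         seed = as.integer(seed)),
    class = "synthetic_ground_truth")
}

check_row_stochastic <- function(m, name, tol = 1e-9) {
  if (any(m < 0)) {
    stop(sprintf("`%s` must be nonnegative", name), call. = FALSE)
  }
  if (any(abs(rowSums(m) - 1) > tol)) {
    stop(sprintf("rows of `%s` must sum to 1 (tolerance %g)", name, tol),
         call. = FALSE)
  }
  invisible(m)
}

#' Simulate a closed-cohort note corpus from planted ground truth
#'
#' Every patient receives at least one note in every quarter. By default a
#' note generated at quarter `t` draws its tokens i.i.d. from the mixture
#' `sum_k prevalence[t, k] * phi_true[k, ]`, so the planted prevalence curve
#' is exactly the expected topic mixture at each quarter and is recoverable
#' in expectation by any consistent estimator. An optional Dirichlet jitter
#' re-samples a per-document mixing vector around the quarter's prevalence
#' row, emulating patient-to-patient heterogeneity.
#'
#' @param spec A [cohort_spec()].
#' @param truth A [synthetic_ground_truth()] whose `prevalence_curves` has
#'   `spec$n_quarters` rows.
#' @param doc_jitter Optional positive scalar: per-document mixing vectors
#'   are drawn from `Dirichlet(doc_jitter * prevalence[t, ])`. `NULL`
#'   (default) uses the quarter's prevalence row directly for every document.
#' @param noise Probability, per clean token, of inserting one extra noise
#'   token (numerals, punctuation fragments, single letters) that the
#'   standard normalizer must remove. Default 0 (clean text).
#' @return A `raw_corpus`: a data frame with columns `doc_id`, `patient_id`,
#'   `quarter`, `text`.
#' @export
generate_corpus <- function(spec, truth, doc_jitter = NULL, noise = 0) {
  stopifnot(inherits(spec, "cohort_spec"),
            inherits(truth, "synthetic_ground_truth"))
  if (nrow(truth$prevalence_curves) != spec$n_quarters) {
    stop("`truth$prevalence_curves` must have `spec$n_quarters` rows ",
         sprintf("(got %d, expected %d)", nrow(truth$prevalence_curves),
                 spec$n_quarters), call. = FALSE)
  }
  if (!is.null(doc_jitter)) assert_positive_scalar(doc_jitter, "doc_jitter")
  if (!is.numeric(noise) || noise < 0 || noise > 1) {
    stop("`noise` must be a probability in [0, 1]", call. = FALSE)
  }
  vocab <- colnames(truth$phi_true)
  if (is.null(vocab)) {
    vocab <- synthetic_vocabulary(ncol(truth$phi_true))
  }
  # tokens the normalizer must strip: numerals, punctuation, length-1 rests
  noise_pool <- c("7", "120/80", "x1", "a", "-", "t2", "..", "q4")

  with_seed(spec$seed, {
    pat_ids <- sprintf("p%0*d", max(4L, nchar(spec$n_patients)),
                       seq_len(spec$n_patients))
    records <- vector("list", spec$n_quarters)
    for (t in seq_len(spec$n_quarters)) {
      n_notes <- draw_counts(spec$notes_per_patient_quarter,
                             spec$n_patients)
      note_pat <- rep(pat_ids, n_notes)
      total_notes <- length(note_pat)
      lens <- draw_counts(spec$doc_length, total_notes)
      prev_t <- truth$prevalence_curves[t, ]
      if (is.null(doc_jitter)) {
        mix_word <- as.vector(prev_t %*% truth$phi_true)
        tokens <- sample.int(length(vocab), sum(lens), replace = TRUE,
                             prob = mix_word)
        note_of_token <- rep(seq_len(total_notes), lens)
        texts <- vapply(split(vocab[tokens], note_of_token),
                        paste, character(1), collapse = " ")
      } else {
        theta_d <- rdirichlet_rows(total_notes, doc_jitter * prev_t)
        texts <- character(total_notes)
        for (i in seq_len(total_notes)) {
          p_i <- as.vector(theta_d[i, ] %*% truth$phi_true)
          toks <- sample.int(length(vocab), lens[i], replace = TRUE,
                             prob = p_i)
          texts[i] <- paste(vocab[toks], collapse = " ")
        }
      }
      if (noise > 0) {
        texts <- vapply(texts, function(txt) {
          toks <- strsplit(txt, " ", fixed = TRUE)[[1]]
          ins <- stats::runif(length(toks)) < noise
          if (any(ins)) {
            extra <- sample(noise_pool, sum(ins), replace = TRUE)
            out <- character(length(toks) + sum(ins))
            pos <- seq_along(toks) + cumsum(ins) - ins
            out[pos] <- toks
            out[pos[ins] + 1L] <- extra
            paste(out, collapse = " ")
          } else {
            txt
          }
        }, character(1), USE.NAMES = FALSE)
      }
      records[[t]] <- data.frame(
        patient_id = note_pat,
        quarter = t,
        text = texts,
        stringsAsFactors = FALSE)
    }
    corpus <- do.call(rbind, records)
    corpus$doc_id <- sprintf("d%0*d", max(6L, nchar(nrow(corpus))),
                             seq_len(nrow(corpus)))
    corpus <- corpus[, c("doc_id", "patient_id", "quarter", "text")]
    rownames(corpus) <- NULL
    class(corpus) <- c("raw_corpus", "data.frame")
    corpus
  })
}

#' Read and write JSON-lines corpora
#'
#' One JSON object per line with keys `doc_id`, `patient_id`, `quarter`,
#' `text` — the interchange format between the simulator and the
#' preprocessing stage.
#'
#' @param corpus A `raw_corpus` data frame.
#' @param path File path.
#' @return `read_corpus_jsonl` returns a `raw_corpus`;
#'   `write_corpus_jsonl` returns `path` invisibly.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  stopifnot(is.data.frame(corpus))
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    jsonlite::toJSON(list(doc_id = corpus$doc_id[i],
                          patient_id = corpus$patient_id[i],
                          quarter = corpus$quarter[i],
                          text = corpus$text[i]),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' @rdname write_corpus_jsonl
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, jsonlite::fromJSON)
  corpus <- data.frame(
    doc_id = vapply(recs, `[[`, character(1), "doc_id"),
    patient_id = vapply(recs, `[[`, character(1), "patient_id"),
    quarter = vapply(recs, function(r) as.integer(r$quarter), integer(1)),
    text = vapply(recs, `[[`, character(1), "text"),
    stringsAsFactors = FALSE)
  class(corpus) <- c("raw_corpus", "data.frame")
  corpus
}

#' Serialize planted ground truth as plain-text matrices
#'
#' Writes `phi_true.tsv`, `prevalence_curves.tsv`, and `truth_spec.json`
#' (trend specs and seed) into `dir`, for use by recovery analyses.
#'
#' @param truth A `synthetic_ground_truth`.
#' @param dir Output directory (created if needed).
#' @return `read_ground_truth` returns a `synthetic_ground_truth`;
#'   `write_ground_truth` returns `dir` invisibly.
#' @export
write_ground_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "synthetic_ground_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(truth$phi_true, file.path(dir, "phi_true.tsv"))
  write_matrix_tsv(truth$prevalence_curves,
                   file.path(dir, "prevalence_curves.tsv"))
  jsonlite::write_json(
    list(trend_specs = truth$trend_specs, seed = truth$seed),
    file.path(dir, "truth_spec.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(dir) {
  phi <- read_matrix_tsv(file.path(dir, "phi_true.tsv"))
  curves <- read_matrix_tsv(file.path(dir, "prevalence_curves.tsv"))
  spec <- jsonlite::fromJSON(file.path(dir, "truth_spec.json"),
                             simplifyDataFrame = FALSE)
  synthetic_ground_truth(phi, curves, trend_specs = spec$trend_specs,
                         seed = spec$seed %||% NA_integer_)
}

write_matrix_tsv <- function(m, path) {
  if (is.null(rownames(m))) rownames(m) <- paste0("row_", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("col_", seq_len(ncol(m)))
  df <- as.data.frame(m)
  utils::write.table(format(df, digits = 17, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  as.matrix(df)
}
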