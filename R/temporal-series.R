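#' Time-stratified topical-prevalence series
#'
#' Averages the per-document topic proportions (theta rows) within each
#' quarterly stratum, producing the T x K matrix whose column k is the
#' length-T time series of mean prevalence of topic k. Because each row is a
#' mean of probability vectors, every row sums to 1: each time point carries
#' a distribution over topics.
#'
#' @param fit A `topic_model_fit`.
#' @param quarters Integer vector: the quarter index (1..`n_quarters`) of
#'   each analysis row of `fit$theta`.
#' @param n_quarters Number of quarterly strata `T`; defaults to
#'   `max(quarters)`. Every quarter must contain at least one document.
#' @param topic_labels Optional length-K labels (e.g. joined top words from
#'   [top_words()]); defaults to `topic_1..topic_K`.
#' @param quarter_labels Optional length-T labels; defaults to `q1..qT`.
#' @param weights Optional nonnegative per-row weights (e.g. note counts of
#'   each patient-quarter row). The default `NULL` takes the unweighted mean
#'   over analysis rows, matching a design in which every patient-quarter
#'   counts once.
#' @return A `temporal_topic_series`: list with `values` (T x K),
#'   `quarter_labels`, `topic_labels`, `model_tag`.
#' @export
topical_time_series <- function(fit, quarters, n_quarters = max(quarters),
                                topic_labels = NULL,
                                quarter_labels = NULL,
                                weights = NULL) {
  stopifnot(inherits(fit, "topic_model_fit"))
  quarters <- as.integer(quarters)
  if (length(quarters) != nrow(fit$theta)) {
    stop("`quarters` must have one entry per theta row", call. = FALSE)
  }
  n_quarters <- assert_count(n_quarters, "n_quarters")
  if (any(quarters < 1L | quarters > n_quarters)) {
    stop("quarter indices must lie in 1..n_quarters", call. = FALSE)
  }
  missing_q <- setdiff(seq_len(n_quarters), unique(quarters))
  if (length(missing_q)) {
    stop("empty stratum: no documents in quarter(s) ",
         paste(missing_q, collapse = ", "), " - cannot average",
         call. = FALSE)
  }
  if (!is.null(weights)) {
    if (length(weights) != nrow(fit$theta) || any(weights < 0)) {
      stop("`weights` must be nonnegative, one per theta row",
           call. = FALSE)
    }
  }
  K <- fit$K
  values <- matrix(NA_real_, n_quarters, K)
  for (t in seq_len(n_quarters)) {
    sel <- quarters == t
    th <- fit$theta[sel, , drop = FALSE]
    if (is.null(weights)) {
      values[t, ] <- colMeans(th)
    } else {
      w <- weights[sel]
      if (sum(w) == 0) {
        stop("all weights zero in quarter ", t, call. = FALSE)
      }
      values[t, ] <- colSums(th * w) / sum(w)
    }
  }
  topic_labels <- topic_labels %||% paste0("topic_", seq_len(K))
  quarter_labels <- quarter_labels %||% paste0("q", seq_len(n_quarters))
  dimnames(values) <- list(quarter_labels, topic_labels)
  structure(
    list(values = values,
         quarter_labels = quarter_labels,
         topic_labels = topic_labels,
         model_tag = fit$model_tag),
    class = "temporal_topic_series")
}

#' Top words per topic
#'
#' For each topic, the `L` vocabulary tokens with the largest phi weight,
#' in decreasing order; ties broken by vocabulary order for determinism.
#'
#' @param fit A `topic_model_fit`.
#' @param vocab A `vocabulary` (or a character vector of tokens aligned to
#'   the columns of `fit$phi`).
#' @param L Number of words per topic (default 5), `1 <= L <= V`.
#' @return A list of length K of character vectors of length `L`.
#' @export
top_words <- function(fit, vocab, L = 5L) {
  stopifnot(inherits(fit, "topic_model_fit"))
  tokens <- if (inherits(vocab, "vocabulary")) vocab$token else
    as.character(vocab)
  v <- ncol(fit$phi)
  if (length(tokens) != v) {
    stop("vocabulary length must equal ncol(phi)", call. = FALSE)
  }
  L <- assert_count(L, "L")
  if (L > v) stop("`L` must not exceed the vocabulary size", call. = FALSE)
  out <- lapply(seq_len(fit$K), function(k) {
    ord <- order(-fit$phi[k, ], seq_len(v))
    tokens[ord[seq_len(L)]]
  })
  names(out) <- paste0("topic_", seq_len(fit$K))
  out
}

#' Topic labels from top words
#'
#' @param fit A `topic_model_fit`.
#' @param vocab A `vocabulary`.
#' @param L Words per label.
#' @param sep Separator between words.
#' @return Character vector of length K.
#' @export
topic_labels <- function(fit, vocab, L = 5L, sep = " ") {
  vapply(top_words(fit, vocab, L), paste, character(1), collapse = sep)
}

#' Ward clustering of topic time series
#'
#' Hierarchically clusters the K topic trajectories (columns of the T x K
#' prevalence matrix, each a length-T point) with the Euclidean distance
#' metric and Ward agglomeration. Merge heights are reported as the square
#' root of the increase in within-cluster sum of squares at each merge, so
#' merging two singleton series at Euclidean distance `e` happens at height
#' `sqrt(1/2) * e`; heights are nondecreasing down the merge table.
#'
#' @param series A `temporal_topic_series` with `K >= 2` topics.
#' @return A `topic_clustering`: list with the `merge` table, `height`
#'   vector, leaf `order`, `labels`, `distance_metric = "euclidean"`,
#'   `method = "ward"`, and the underlying `hclust` object (heights on the
#'   same scale) for dendrogram plotting.
#' @export
cluster_topic_series <- function(series) {
  stopifnot(inherits(series, "temporal_topic_series"))
  K <- ncol(series$values)
  if (K < 2L) {
    stop("clustering needs at least 2 topics", call. = FALSE)
  }
  pts <- t(series$values)            # K points in T dimensions
  rownames(pts) <- series$topic_labels
  hc <- stats::hclust(stats::dist(pts, method = "euclidean"),
                      method = "ward.D2")
  # ward.D2 heights equal sqrt(2 * increase in within-cluster SS)
  hc$height <- hc$height / sqrt(2)
  structure(
    list(merge = hc$merge,
         height = hc$height,
         order = hc$order,
         labels = hc$labels,
         distance_metric = "euclidean",
         method = "ward",
         hclust = hc),
    class = "topic_clustering")
}

#' Percentile bootstrap bands for the prevalence series
#'
#' Within each quarterly stratum, documents are resampled with replacement
#' and the stratum mean theta recomputed, giving percentile intervals for
#' every (quarter, topic) cell. Intervals are widened, if necessary, to
#' contain the point estimate. A stratum holding a single document yields a
#' degenerate interval at the point (with a warning).
#'
#' @param fit A `topic_model_fit`.
#' @param quarters Per-document quarter indices (as in
#'   [topical_time_series()]).
#' @param n_quarters Number of strata.
#' @param n_boot Bootstrap resamples per stratum (>= 100; default 500).
#' @param level Interval level in (0, 1) (default 0.95).
#' @param seed Integer seed; intervals are reproducible from it.
#' @return A `prevalence_ci`: list with T x K matrices `estimate`, `lower`,
#'   `upper`, plus `level`, `n_boot`, `seed`.
#' @export
bootstrap_prevalence_ci <- function(fit, quarters,
                                    n_quarters = max(quarters),
                                    n_boot = 500L, level = 0.95,
                                    seed = 1L) {
  stopifnot(inherits(fit, "topic_model_fit"))
  n_boot <- assert_count(n_boot, "n_boot", min = 100L)
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    stop("`level` must lie strictly between 0 and 1", call. = FALSE)
  }
  series <- topical_time_series(fit, quarters, n_quarters)
  est <- series$values
  K <- ncol(est)
  lower <- upper <- matrix(NA_real_, n_quarters, K,
                           dimnames = dimnames(est))
  a <- (1 - level) / 2
  degenerate <- FALSE
  with_seed(seed, {
    for (t in seq_len(n_quarters)) {
      idx <- which(quarters == t)
      n <- length(idx)
      if (n == 1L) {
        degenerate <- TRUE
        lower[t, ] <- upper[t, ] <- est[t, ]
        next
      }
      samp <- matrix(idx[sample.int(n, n * n_boot, replace = TRUE)],
                     nrow = n, ncol = n_boot)
      for (k in seq_len(K)) {
        boots <- colMeans(matrix(fit$theta[samp, k], nrow = n))
        qs <- stats::quantile(boots, c(a, 1 - a), names = FALSE, type = 7)
        lower[t, k] <- min(qs[1], est[t, k])
        upper[t, k] <- max(qs[2], est[t, k])
      }
    }
  })
  if (degenerate) {
    warning("one or more strata contain a single document: ",
            "their intervals collapse to the point estimate",
            call. = FALSE)
  }
  structure(
    list(estimate = est, lower = lower, upper = upper,
         level = level, n_boot = n_boot, seed = as.integer(seed)),
    class = "prevalence_ci")
}

#' Export a temporal series and linkage table as delimited text
#'
#' @param series A `temporal_topic_series`.
#' @param path Output TSV path (header row of topic labels).
#' @return The path, invisibly.
#' @export
write_series_tsv <- function(series, path) {
  stopifnot(inherits(series, "temporal_topic_series"))
  write_matrix_tsv(series$values, path)
}

#' @rdname write_series_tsv
#' @param clustering A `topic_clustering`.
#' @export
write_linkage_tsv <- function(clustering, path) {
  stopifnot(inherits(clustering, "topic_clustering"))
  df <- data.frame(member_a = clustering$merge[, 1],
                   member_b = clustering$merge[, 2],
                   height = clustering$height)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
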