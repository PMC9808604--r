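#' Co-occurrence statistics for coherence scoring
#'
#' Collects, for a set of candidate words, (a) whole-document frequencies
#' `D(w)` and joint frequencies `D(w_i, w_j)` (used by the UMass measure)
#' and (b) sliding-window occurrence probabilities `P(w)`, `P(w_i, w_j)`
#' (used by UCI and NPMI). Windows of the given width step one token at a
#' time within each document; a document shorter than the window contributes
#' a single window. Probabilities are window counts over the total number of
#' windows in the reference corpus.
#'
#' @param corpus A `tokenized_corpus`, or a list of token vectors.
#' @param words Character vector of candidate words (typically the union of
#'   all topics' top words).
#' @param window Sliding-window width (>= 2; default 10).
#' @return A `cooccurrence_counts` object.
#' @export
count_cooccurrence <- function(corpus, words, window = 10L) {
  docs <- if (inherits(corpus, "tokenized_corpus")) corpus$tokens else
    corpus
  if (!is.list(docs)) stop("`corpus` must be tokenized", call. = FALSE)
  words <- unique(as.character(words))
  if (length(words) == 0L) {
    stop("`words` must be nonempty", call. = FALSE)
  }
  window <- assert_count(window, "window", min = 2L)
  m <- length(words)
  doc_freq <- integer(m)
  pair_doc <- matrix(0, m, m)
  win_freq <- numeric(m)
  pair_win <- matrix(0, m, m)
  n_windows <- 0

  for (toks in docs) {
    hit <- match(toks, words)
    present <- sort(unique(hit[!is.na(hit)]))
    if (length(present)) {
      doc_freq[present] <- doc_freq[present] + 1L
      pair_doc[present, present] <- pair_doc[present, present] + 1
    }
    n <- length(toks)
    nw <- max(1L, n - window + 1L)
    n_windows <- n_windows + nw
    if (length(present) == 0L) next
    if (n <= window) {
      # one window spanning the whole document
      win_freq[present] <- win_freq[present] + 1
      pair_win[present, present] <- pair_win[present, present] + 1
    } else {
      # indicator of word j in window starting at i, via cumulative sums
      ind <- matrix(FALSE, nw, length(present))
      for (jj in seq_along(present)) {
        occ <- as.integer(hit == present[jj] & !is.na(hit))
        cs <- c(0L, cumsum(occ))
        ind[, jj] <- (cs[(window + 1L):(n + 1L)] -
                        cs[1L:nw]) > 0L
      }
      win_freq[present] <- win_freq[present] + colSums(ind)
      pair_win[present, present] <-
        pair_win[present, present] + crossprod(ind)
    }
  }
  names(doc_freq) <- names(win_freq) <- words
  dimnames(pair_doc) <- dimnames(pair_win) <- list(words, words)
  structure(
    list(words = words,
         doc_freq = doc_freq, pair_doc_freq = pair_doc,
         window_freq = win_freq, pair_window_freq = pair_win,
         n_docs = length(docs), n_windows = n_windows,
         window = window),
    class = "cooccurrence_counts")
}

#' Topic coherence (UMass, UCI, NPMI)
#'
#' Scores each topic's top-word list by how strongly its words co-occur in
#' the reference corpus, then averages over topics. With natural logarithms
#' throughout and a small `epsilon` guarding zero counts:
#' \describe{
#'   \item{umass}{mean over ordered pairs (i > j, j the higher-ranked word)
#'     of `log((D(w_i, w_j) + eps) / D(w_j))`, on whole-document counts.}
#'   \item{uci}{mean over unordered pairs of
#'     `log((P(w_i, w_j) + eps) / (P(w_i) P(w_j)))`, on sliding-window
#'     probabilities.}
#'   \item{npmi}{the UCI log-ratio divided by `-log(P(w_i, w_j) + eps)`,
#'     normalizing pointwise mutual information to `[-1, 1]`. A pair present
#'     in every window carries no information and scores 0.}
#' }
#' A word absent from the reference corpus is treated as having frequency
#' zero, with `epsilon` guarding the logarithms.
#'
#' @param topics List of per-topic ordered top-word vectors (each of length
#'   >= 2), e.g. from [top_words()].
#' @param counts A `cooccurrence_counts` covering the topics' words.
#' @param measure One of `"umass"`, `"uci"`, `"npmi"`.
#' @param epsilon Small positive smoothing constant (default 1e-12).
#' @return A `coherence_score`: list with `per_topic` scores, the model
#'   `mean`, and the `measure` name.
#' @export
coherence <- function(topics, counts,
                      measure = c("umass", "uci", "npmi"),
                      epsilon = 1e-12) {
  measure <- match.arg(measure)
  stopifnot(inherits(counts, "cooccurrence_counts"))
  if (!is.list(topics)) topics <- list(topics)
  assert_positive_scalar(epsilon, "epsilon")
  per_topic <- vapply(topics, function(ws) {
    ws <- as.character(ws)
    if (length(ws) < 2L) {
      stop("each topic needs at least 2 words", call. = FALSE)
    }
    idx <- match(ws, counts$words)
    if (anyNA(idx)) {
      stop("topic word(s) missing from the co-occurrence counts: ",
           paste(ws[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    L <- length(ws)
    terms <- c()
    if (measure == "umass") {
      for (i in 2:L) {
        for (j in 1:(i - 1)) {
          dij <- counts$pair_doc_freq[idx[i], idx[j]]
          dj <- counts$doc_freq[idx[j]]
          denom <- if (dj > 0) dj else epsilon
          terms <- c(terms, log((dij + epsilon) / denom))
        }
      }
    } else {
      nw <- counts$n_windows
      for (i in 1:(L - 1)) {
        for (j in (i + 1):L) {
          pij <- counts$pair_window_freq[idx[i], idx[j]] / nw
          pi_ <- counts$window_freq[idx[i]] / nw
          pj <- counts$window_freq[idx[j]] / nw
          denom <- pi_ * pj
          if (denom == 0) denom <- epsilon
          val <- log((pij + epsilon) / denom)
          if (measure == "npmi") {
            val <- if (pij >= 1) 0 else val / (-log(pij + epsilon))
          }
          terms <- c(terms, val)
        }
      }
    }
    mean(terms)
  }, numeric(1))
  structure(
    list(per_topic = per_topic, mean = mean(per_topic), measure = measure,
         epsilon = epsilon),
    class = "coherence_score")
}

#' Bag of topic words
#'
#' The multiset of the top-`L` words of each of the K topics — `K * L`
#' tokens in total, duplicates preserved. The summary object on which topic
#' diversity, recurring words and Jaccard concordance operate.
#'
#' @param topics List of K per-topic word vectors, each of length `L` (e.g.
#'   from [top_words()]).
#' @return A `topic_bag`: character vector of length `K * L` with
#'   attributes `K` and `L`.
#' @export
topic_bag <- function(topics) {
  if (!is.list(topics) || length(topics) == 0L) {
    stop("`topics` must be a nonempty list of word vectors", call. = FALSE)
  }
  L <- unique(lengths(topics))
  if (length(L) != 1L) {
    stop("all topics must contribute the same number of words",
         call. = FALSE)
  }
  structure(unlist(topics, use.names = FALSE),
            K = length(topics), L = L, class = "topic_bag")
}

#' Topic diversity
#'
#' The fraction of unique words in a bag of `K * L` topic words. A fully
#' redundant model (all topics sharing the same words) scores `L / (K * L)`;
#' a model whose topics never share a top word scores 1.
#'
#' @param bag A `topic_bag` (or plain character vector).
#' @return List with `n_unique`, `n_total`, `diversity` (fraction) and
#'   `percent`.
#' @export
topic_diversity <- function(bag) {
  words <- as.character(bag)
  if (length(words) == 0L) stop("empty bag", call. = FALSE)
  n_unique <- length(unique(words))
  n_total <- length(words)
  list(n_unique = n_unique, n_total = n_total,
       diversity = n_unique / n_total,
       percent = 100 * n_unique / n_total)
}

#' Jaccard concordance between models' topic-word bags
#'
#' Pairwise `|A intersect B| / |A union B|` over the deduplicated word sets
#' of each bag: 1 for identical vocabular coverage, 0 for disjoint topical
#' vocabularies.
#'
#' @param bags Named list of two or more `topic_bag`s (or character
#'   vectors).
#' @return Symmetric matrix of Jaccard coefficients with unit diagonal.
#' @export
jaccard_concordance <- function(bags) {
  if (!is.list(bags) || length(bags) < 2L) {
    stop("need at least 2 bags", call. = FALSE)
  }
  sets <- lapply(bags, function(b) unique(as.character(b)))
  n <- length(sets)
  nm <- names(bags) %||% paste0("model_", seq_len(n))
  out <- matrix(1, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      jac <- length(intersect(sets[[i]], sets[[j]])) /
        length(union(sets[[i]], sets[[j]]))
      out[i, j] <- out[j, i] <- jac
    }
  }
  out
}

#' Most frequently recurring words in a topic bag
#'
#' The words that appear in the top lists of many topics at once — a rough
#' map of the semantic concepts a model repeatedly singles out.
#'
#' @param bag A `topic_bag`.
#' @param top_n Number of words to report; ties broken alphabetically.
#' @return Data frame with columns `word`, `count`.
#' @export
recurring_words <- function(bag, top_n = 5L) {
  top_n <- assert_count(top_n, "top_n")
  words <- as.character(bag)
  counts <- table(words)
  ord <- order(-as.integer(counts), names(counts))
  counts <- counts[ord]
  take <- seq_len(min(top_n, length(counts)))
  data.frame(word = names(counts)[take],
             count = as.integer(counts)[take],
             stringsAsFactors = FALSE)
}
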