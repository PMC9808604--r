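# Shared fixtures and independent oracles, built in code at test time.

# A tiny tokenized corpus from explicit token vectors.
toy_tokenized <- function(token_lists,
                          patient = rep("p1", length(token_lists)),
                          quarter = rep(1L, length(token_lists))) {
  out <- data.frame(
    doc_id = sprintf("d%03d", seq_along(token_lists)),
    patient_id = patient,
    quarter = as.integer(quarter),
    stringsAsFactors = FALSE)
  out$tokens <- token_lists
  class(out) <- c("tokenized_corpus", "data.frame")
  out
}

# Standard recovery corpus: V=200, K*=5 well-separated planted topics, one
# seasonal (amplitude 0.5, period 4), 100 patients x 20 quarters -> 2,000
# patient-quarter documents. Documents are genuine admixtures: per-document
# mixing vectors are Dirichlet with the quarter's prevalence row as
# concentration (doc_jitter = 1), so E[theta_d] equals the planted curve
# while individual documents stay focused enough to identify the topics.
recovery_setup <- function(seed) {
  k_true <- 5L
  phi <- make_topics(k_true, 200L, concentration = 0.05, seed = seed)
  trends <- c(list(trend_seasonal(0.5, period = 4, phase = 0)),
              rep(list(trend_constant()), k_true - 1L))
  curves <- make_prevalence_curves(20L, trends)
  truth <- synthetic_ground_truth(phi, curves, trend_specs = trends,
                                  seed = seed)
  spec <- cohort_spec(100L, 20L, seed = seed)
  corpus <- generate_corpus(spec, truth, doc_jitter = 1)
  tok <- tokenize_corpus(corpus)
  vocab <- build_vocabulary(tok)
  dtm <- build_dtm(tok, vocab, level = "patient_quarter", n_quarters = 20L)
  list(truth = truth, corpus = corpus, tok = tok, vocab = vocab, dtm = dtm)
}

# Fit both models on a recovery corpus and measure planted-topic recovery;
# cached so several test blocks can share one computation per seed.
.recovery_cache <- new.env(parent = emptyenv())
recovery_fits <- function(seed) {
  key <- paste0("seed_", seed)
  if (!exists(key, envir = .recovery_cache)) {
    setup <- recovery_setup(seed)
    phi_true <- align_truth_phi(setup$truth, setup$dtm)
    curves <- setup$truth$prevalence_curves
    quarters <- setup$dtm$row_meta$quarter

    fits <- list(
      nmf = normalize_nmf(fit_nmf(setup$dtm, 5, seed = seed)),
      lda = fit_lda(setup$dtm,
                    lda_config(5, alpha = 0.1, beta = 0.01, seed = seed)))
    res <- lapply(fits, function(fit) {
      m <- match_topics(fit$phi, phi_true)
      series <- topical_time_series(fit, quarters, 20L)
      seasonal_hat <- m$estimated[m$planted == 1]
      list(fit = fit, match = m, mean_tv = mean(m$tv),
           series = series,
           spearman_seasonal = stats::cor(
             series$values[, seasonal_hat], curves[, 1],
             method = "spearman"))
    })
    assign(key, list(setup = setup, phi_true = phi_true, models = res),
           envir = .recovery_cache)
  }
  get(key, envir = .recovery_cache)
}

# Align planted phi columns with the DTM vocabulary ordering.
align_truth_phi <- function(truth, dtm) {
  idx <- match(dtm$vocabulary$token, colnames(truth$phi_true))
  stopifnot(!anyNA(idx))
  phi <- truth$phi_true[, idx, drop = FALSE]
  phi / rowSums(phi)
}

# ---- brute-force coherence oracle -----------------------------------------
# Independent pair-enumeration implementation operating directly on token
# lists; used to validate the package's counting + scoring path.
oracle_coherence <- function(topics, docs, measure, window = 10L,
                             epsilon = 1e-12) {
  all_windows <- list()
  for (toks in docs) {
    n <- length(toks)
    if (n <= window) {
      all_windows[[length(all_windows) + 1L]] <- toks
    } else {
      for (s in 1:(n - window + 1L)) {
        all_windows[[length(all_windows) + 1L]] <- toks[s:(s + window - 1L)]
      }
    }
  }
  nw <- length(all_windows)
  d_of <- function(w) sum(vapply(docs, function(d) w %in% d, logical(1)))
  d_pair <- function(a, b) {
    sum(vapply(docs, function(d) (a %in% d) && (b %in% d), logical(1)))
  }
  p_of <- function(w) {
    sum(vapply(all_windows, function(d) w %in% d, logical(1))) / nw
  }
  p_pair <- function(a, b) {
    sum(vapply(all_windows,
               function(d) (a %in% d) && (b %in% d), logical(1))) / nw
  }
  scores <- vapply(topics, function(ws) {
    L <- length(ws)
    terms <- c()
    if (measure == "umass") {
      for (i in 2:L) for (j in 1:(i - 1)) {
        dj <- d_of(ws[j])
        denom <- if (dj > 0) dj else epsilon
        terms <- c(terms, log((d_pair(ws[i], ws[j]) + epsilon) / denom))
      }
    } else {
      for (i in 1:(L - 1)) for (j in (i + 1):L) {
        pij <- p_pair(ws[i], ws[j])
        denom <- p_of(ws[i]) * p_of(ws[j])
        if (denom == 0) denom <- epsilon
        val <- log((pij + epsilon) / denom)
        if (measure == "npmi") {
          val <- if (pij >= 1) 0 else val / (-log(pij + epsilon))
        }
        terms <- c(terms, val)
      }
    }
    mean(terms)
  }, numeric(1))
  list(per_topic = scores, mean = mean(scores))
}

# ---- sequential-construction oracle for the collapsed LDA joint -----------
# p(w, z | alpha, beta) built token by token from Polya-urn predictive
# probabilities; independent of the lgamma closed form it checks.
oracle_joint_prob <- function(doc, word, z, D, V, K, alpha, beta) {
  if (length(alpha) == 1L) alpha <- rep(alpha, K)
  if (length(beta) == 1L) beta <- rep(beta, V)
  n_dk <- matrix(0, D, K)
  n_kv <- matrix(0, K, V)
  n_k <- numeric(K)
  n_d <- numeric(D)
  p <- 1
  for (n in seq_along(doc)) {
    d <- doc[n]; v <- word[n]; k <- z[n]
    p_z <- (n_dk[d, k] + alpha[k]) / (n_d[d] + sum(alpha))
    p_w <- (n_kv[k, v] + beta[v]) / (n_k[k] + sum(beta))
    p <- p * p_z * p_w
    n_dk[d, k] <- n_dk[d, k] + 1
    n_kv[k, v] <- n_kv[k, v] + 1
    n_k[k] <- n_k[k] + 1
    n_d[d] <- n_d[d] + 1
  }
  p
}
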