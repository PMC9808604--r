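#' Configuration for the collapsed Gibbs LDA sampler
#'
#' Latent Dirichlet allocation places symmetric (or per-dimension) Dirichlet
#' priors on the per-document topic mixtures (concentration `alpha`) and the
#' per-topic word distributions (concentration `beta`). The collapsed Gibbs
#' sampler integrates theta and phi out analytically and resamples only the
#' per-token topic indicators from count statistics.
#'
#' @param K Number of topics.
#' @param alpha Document-topic Dirichlet concentration: a positive scalar
#'   (symmetric prior) or a length-`K` vector. Default `1/K`.
#' @param beta Topic-word Dirichlet concentration: a positive scalar or a
#'   length-`V` vector. Default `0.01`.
#' @param n_iter Total Gibbs sweeps (default 400).
#' @param burn_in Sweeps discarded before averaging posterior-mean
#'   estimators (default 200; must be `< n_iter`).
#' @param seed Integer seed; one root seed drives the whole sweep stream,
#'   so runs are bit-reproducible.
#' @return An `lda_config` object.
#' @export
lda_config <- function(K, alpha = 1 / K, beta = 0.01,
                       n_iter = 400L, burn_in = 200L, seed = 1L) {
  K <- assert_count(K, "K")
  if (!is.numeric(alpha) || any(alpha <= 0) ||
      !(length(alpha) %in% c(1L, K))) {
    stop("`alpha` must be positive, scalar or length K", call. = FALSE)
  }
  if (!is.numeric(beta) || any(beta <= 0)) {
    stop("`beta` must be positive, scalar or length V", call. = FALSE)
  }
  n_iter <- assert_count(n_iter, "n_iter")
  burn_in <- assert_count(burn_in, "burn_in", min = 0L)
  if (burn_in >= n_iter) {
    stop("`burn_in` must be smaller than `n_iter`", call. = FALSE)
  }
  structure(
    list(K = K, alpha = as.numeric(alpha), beta = as.numeric(beta),
         n_iter = n_iter, burn_in = burn_in, seed = as.integer(seed)),
    class = "lda_config")
}

#' Fit LDA by collapsed Gibbs sampling
#'
#' Runs collapsed Gibbs sweeps over every token position, resampling the
#' topic indicator from
#' `p(z = k) \propto (n_dk + alpha_k) (n_kv + beta_v) / (n_k + sum(beta))`
#' with counts excluding the current token. After burn-in, the posterior
#' mean estimators `theta[d,k] = (n_dk + alpha_k) / (n_d + sum(alpha))` and
#' `phi[k,v] = (n_kv + beta_v) / (n_k + sum(beta))` are averaged over all
#' retained sweeps. Documents with no in-vocabulary tokens receive the
#' normalized prior as their theta row.
#'
#' @param dtm A `dtm` from [build_dtm()] or a nonnegative integer matrix.
#' @param config An [lda_config()].
#' @return A `topic_model_fit` with `model_tag = "lda"`. The per-sweep
#'   collapsed log-likelihood trace sits in `diagnostics$log_lik_trace`, and
#'   the final sampler state is retrievable with [gibbs_state()].
#' @export
fit_lda <- function(dtm, config) {
  stopifnot(inherits(config, "lda_config"))
  x <- if (inherits(dtm, "dtm")) dtm$counts else dtm
  if (!(is.matrix(x) || inherits(x, "Matrix"))) {
    stop("`dtm` must be a dtm object or a numeric matrix", call. = FALSE)
  }
  if (ncol(x) < 1L) stop("empty vocabulary", call. = FALSE)
  if (sum(x) == 0) stop("dtm is empty: no tokens to sample", call. = FALSE)
  d_n <- nrow(x)
  v_n <- ncol(x)
  beta <- config$beta
  if (length(beta) == 1L) beta <- rep(beta, v_n)
  if (length(beta) != v_n) {
    stop("`beta` must be scalar or length V", call. = FALSE)
  }
  alpha <- config$alpha
  if (length(alpha) == 1L) alpha <- rep(alpha, config$K)

  trip <- Matrix::summary(methods::as(x, "TsparseMatrix"))
  trip <- trip[trip$x > 0, , drop = FALSE]
  ord <- order(trip$i, trip$j)
  reps <- as.integer(round(trip$x[ord]))
  doc <- rep.int(trip$i[ord] - 1L, reps)
  word <- rep.int(trip$j[ord] - 1L, reps)

  res <- with_seed(config$seed, {
    .lda_gibbs_cpp(doc, word, d_n, v_n, config$K, alpha, beta,
                   config$n_iter, config$burn_in)
  })

  theta <- res$theta
  phi <- res$phi
  rownames(theta) <- rownames(x)
  colnames(phi) <- colnames(x)
  rownames(phi) <- paste0("topic_", seq_len(config$K))
  colnames(theta) <- rownames(phi)
  # guard against accumulated floating-point drift in the averaged rows
  theta <- theta / rowSums(theta)
  phi <- phi / rowSums(phi)

  fit <- topic_model_fit(
    theta = theta, phi = phi, model_tag = "lda", K = config$K,
    seed = config$seed,
    diagnostics = list(log_lik_trace = res$log_lik_trace,
                       retained_sweeps = res$retained))
  attr(fit, "gibbs_state") <- structure(
    list(z = as.integer(res$z) + 1L,
         doc = doc + 1L, word = word + 1L,
         n_dk = res$n_dk, n_kv = res$n_kv,
         n_k = as.integer(res$n_k), n_d = as.integer(res$n_d),
         D = d_n, V = v_n, K = config$K),
    class = "gibbs_state")
  fit
}

#' Final Gibbs sampler state of an LDA fit
#'
#' @param fit A `topic_model_fit` returned by [fit_lda()].
#' @return A `gibbs_state`: token-level topic indicators `z` (1-based) with
#'   parallel `doc`/`word` indices and the count matrices `n_dk`, `n_kv`,
#'   `n_k`, `n_d`.
#' @export
gibbs_state <- function(fit) {
  st <- attr(fit, "gibbs_state")
  if (is.null(st)) {
    stop("no Gibbs state attached: fit was not produced by fit_lda()",
         call. = FALSE)
  }
  st
}

#' Build a Gibbs state from explicit topic assignments
#'
#' Used for enumeration-based checks: given token positions and a complete
#' topic assignment, reconstructs the count statistics of the collapsed
#' sampler.
#'
#' @param doc,word Parallel 1-based document and word indices per token.
#' @param z 1-based topic indicator per token.
#' @param D,V,K Numbers of documents, vocabulary words and topics.
#' @return A `gibbs_state`.
#' @export
make_gibbs_state <- function(doc, word, z, D, V, K) {
  stopifnot(length(doc) == length(word), length(doc) == length(z))
  n_dk <- matrix(0L, D, K)
  n_kv <- matrix(0L, K, V)
  for (n in seq_along(doc)) {
    n_dk[doc[n], z[n]] <- n_dk[doc[n], z[n]] + 1L
    n_kv[z[n], word[n]] <- n_kv[z[n], word[n]] + 1L
  }
  structure(
    list(z = as.integer(z), doc = as.integer(doc), word = as.integer(word),
         n_dk = n_dk, n_kv = n_kv,
         n_k = as.integer(rowSums(n_kv)), n_d = as.integer(rowSums(n_dk)),
         D = D, V = V, K = K),
    class = "gibbs_state")
}

#' Collapsed joint log-likelihood of an LDA state
#'
#' Computes `log p(w, z | alpha, beta)` in the Dirichlet-multinomial closed
#' form (theta and phi integrated out):
#' a product of document-level and topic-level Dirichlet normalizing-constant
#' ratios, evaluated as sums of log-Gamma terms. Used as the sampler's
#' convergence diagnostic.
#'
#' @param state A `gibbs_state`.
#' @param config The [lda_config()] supplying the priors.
#' @return A single numeric log-probability.
#' @export
log_likelihood <- function(state, config) {
  stopifnot(inherits(state, "gibbs_state"), inherits(config, "lda_config"))
  K <- state$K
  V <- state$V
  alpha <- config$alpha
  if (length(alpha) == 1L) alpha <- rep(alpha, K)
  beta <- config$beta
  if (length(beta) == 1L) beta <- rep(beta, V)
  a_sum <- sum(alpha)
  b_sum <- sum(beta)
  doc_part <-
    sum(lgamma(a_sum) - lgamma(a_sum + state$n_d)) +
    sum(lgamma(sweep(state$n_dk, 2, alpha, `+`))) -
    state$D * sum(lgamma(alpha))
  topic_part <-
    sum(lgamma(b_sum) - lgamma(b_sum + state$n_k)) +
    sum(lgamma(sweep(state$n_kv, 2, beta, `+`))) -
    K * sum(lgamma(beta))
  doc_part + topic_part
}
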