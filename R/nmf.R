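#' Nonnegative matrix factorization by multiplicative updates
#'
#' Factorizes the document-term matrix `X` (D x V) into nonnegative
#' `W` (D x K) and `H` (K x V) minimizing the Frobenius loss
#' `||X - W H||_F^2`, using the Lee-Seung multiplicative update rules. The
#' updates never leave the nonnegative orthant and the loss is nonincreasing
#' at every iteration, which is asserted on every fit. Row-normalizing `W`
#' and `H` afterwards (see [normalize_nmf()]) turns them into the
#' compositional matrices theta (per-document topic proportions) and phi
#' (per-topic word proportions).
#'
#' @param dtm A `dtm` from [build_dtm()], or a nonnegative numeric matrix.
#' @param K Number of topics, `1 <= K <= min(D, V)`.
#' @param max_iter Maximum number of update iterations (default 500).
#' @param tol Relative loss-change convergence threshold (default 1e-5).
#' @param seed Integer seed for the random initialization. Entries of `W`
#'   and `H` start i.i.d. uniform(0,1) scaled by `sqrt(mean(X)/K)`, so the
#'   initial reconstruction is on the scale of the data.
#' @return An `nmf_fit`: list with `W`, `H`, `loss_trace`, `K`, `seed`,
#'   `n_iter`, `converged`.
#' @export
fit_nmf <- function(dtm, K, max_iter = 500L, tol = 1e-5, seed = 1L) {
  x <- if (inherits(dtm, "dtm")) dtm$counts else dtm
  if (!(is.matrix(x) || inherits(x, "Matrix"))) {
    stop("`dtm` must be a dtm object or a numeric matrix", call. = FALSE)
  }
  if (any(x < 0)) stop("input matrix must be nonnegative", call. = FALSE)
  K <- assert_count(K, "K")
  max_iter <- assert_count(max_iter, "max_iter")
  if (!is.numeric(tol) || tol < 0) {
    stop("`tol` must be nonnegative", call. = FALSE)
  }
  d <- nrow(x)
  v <- ncol(x)
  if (K > min(d, v)) {
    stop(sprintf("K = %d exceeds matrix dimensions (%d x %d)", K, d, v),
         call. = FALSE)
  }
  xnorm2 <- sum(x^2)
  if (xnorm2 == 0) {
    stop("degenerate input: the matrix is all zero", call. = FALSE)
  }
  eps <- 1e-12
  mean_x <- sum(x) / (as.double(d) * v)
  scale <- sqrt(mean_x / K)

  init <- with_seed(seed, {
    list(W = matrix(stats::runif(d * K), d, K) * scale,
         H = matrix(stats::runif(K * v), K, v) * scale)
  })
  W <- init$W
  H <- init$H

  loss_trace <- numeric(max_iter)
  prev_loss <- Inf
  converged <- FALSE
  n_iter <- max_iter
  for (it in seq_len(max_iter)) {
    # H update: H <- H * (W'X) / (W'W H)
    WtX <- as.matrix(Matrix::crossprod(W, x))
    WtW <- crossprod(W)
    H <- H * WtX / (WtW %*% H + eps)
    # W update: W <- W * (X H') / (W H H')
    XHt <- as.matrix(x %*% t(H))
    HHt <- tcrossprod(H)
    W <- W * XHt / (W %*% HHt + eps)
    # Frobenius loss via the trace identity, avoiding a dense D x V product
    WtX <- as.matrix(Matrix::crossprod(W, x))
    loss <- xnorm2 - 2 * sum(WtX * H) + sum(crossprod(W) * tcrossprod(H))
    loss <- max(loss, 0)
    loss_trace[it] <- loss
    if (is.finite(prev_loss) && prev_loss > 0 &&
        abs(prev_loss - loss) / prev_loss < tol) {
      converged <- TRUE
      n_iter <- it
      break
    }
    prev_loss <- loss
  }
  structure(
    list(W = W, H = H,
         loss_trace = loss_trace[seq_len(n_iter)],
         K = K, seed = as.integer(seed),
         n_iter = n_iter, converged = converged),
    class = "nmf_fit")
}

#' Compositional normalization of an NMF fit
#'
#' Divides every row of `W` and `H` by its row sum, yielding the
#' row-stochastic matrices theta and phi of a topic model. All-zero rows
#' (a document or topic that received no mass) map to the uniform vector.
#' The result is invariant to the scale indeterminacy of NMF: jointly
#' rescaling column `k` of `W` by `c > 0` and row `k` of `H` by `1/c`
#' leaves phi unchanged.
#'
#' @param fit An `nmf_fit` from [fit_nmf()].
#' @return A `topic_model_fit` with `model_tag = "nmf"`.
#' @export
normalize_nmf <- function(fit) {
  stopifnot(inherits(fit, "nmf_fit"))
  theta <- row_normalize(fit$W)
  phi <- row_normalize(fit$H)
  topic_model_fit(
    theta = theta, phi = phi, model_tag = "nmf", K = fit$K,
    seed = fit$seed,
    diagnostics = list(final_loss = fit$loss_trace[length(fit$loss_trace)],
                       n_iter = fit$n_iter,
                       converged = fit$converged))
}

#' Model-agnostic topic-model fit container
#'
#' Both estimators (NMF after normalization, LDA posterior means) expose
#' their results through this common contract: `theta` (documents x topics)
#' and `phi` (topics x words), each row-stochastic.
#'
#' @param theta Documents x K matrix, rows summing to 1.
#' @param phi K x V matrix, rows summing to 1.
#' @param model_tag `"nmf"` or `"lda"`.
#' @param K Number of topics.
#' @param seed Seed the fit was run under.
#' @param diagnostics Free-form list of numeric fit diagnostics.
#' @return A `topic_model_fit` object.
#' @export
topic_model_fit <- function(theta, phi, model_tag, K,
                            seed = NA_integer_, diagnostics = list()) {
  theta <- as.matrix(theta)
  phi <- as.matrix(phi)
  if (ncol(theta) != K || nrow(phi) != K) {
    stop("theta/phi dimensions inconsistent with K", call. = FALSE)
  }
  check_row_stochastic(theta, "theta")
  check_row_stochastic(phi, "phi")
  if (!model_tag %in% c("nmf", "lda")) {
    stop("`model_tag` must be 'nmf' or 'lda'", call. = FALSE)
  }
  structure(
    list(theta = theta, phi = phi, model_tag = model_tag, K = as.integer(K),
         seed = as.integer(seed), diagnostics = diagnostics),
    class = "topic_model_fit")
}

#' @export
print.topic_model_fit <- function(x, ...) {
  cat(sprintf("Topic model fit (%s): K = %d, %d documents, V = %d\n",
              toupper(x$model_tag), x$K, nrow(x$theta), ncol(x$phi)))
  invisible(x)
}
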