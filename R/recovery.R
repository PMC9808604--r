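#' Total-variation distance between probability vectors
#'
#' @param p,q Probability vectors of equal length.
#' @return `0.5 * sum(|p - q|)`, in `[0, 1]`.
#' @export
total_variation <- function(p, q) {
  if (length(p) != length(q)) stop("length mismatch", call. = FALSE)
  0.5 * sum(abs(p - q))
}

#' Greedy one-to-one matching of estimated to planted topics
#'
#' Topic labels are exchangeable, so recovery is judged after aligning the
#' estimated topic-word rows with the planted ones. Pairs are matched
#' greedily by increasing total-variation distance, each estimated and each
#' planted topic used at most once.
#'
#' @param phi_hat Estimated K x V row-stochastic matrix.
#' @param phi_true Planted K* x V row-stochastic matrix.
#' @return A data frame with one row per matched pair: `estimated`
#'   (row of `phi_hat`), `planted` (row of `phi_true`), `tv` (the
#'   total-variation distance of the pair); `min(K, K*)` rows, ordered as
#'   matched.
#' @export
match_topics <- function(phi_hat, phi_true) {
  if (ncol(phi_hat) != ncol(phi_true)) {
    stop("vocabulary dimensions differ", call. = FALSE)
  }
  k_hat <- nrow(phi_hat)
  k_true <- nrow(phi_true)
  d <- matrix(NA_real_, k_hat, k_true)
  for (i in seq_len(k_hat)) {
    for (j in seq_len(k_true)) {
      d[i, j] <- total_variation(phi_hat[i, ], phi_true[j, ])
    }
  }
  n_pairs <- min(k_hat, k_true)
  est <- integer(n_pairs)
  pla <- integer(n_pairs)
  tv <- numeric(n_pairs)
  free_i <- rep(TRUE, k_hat)
  free_j <- rep(TRUE, k_true)
  for (r in seq_len(n_pairs)) {
    dd <- d
    dd[!free_i, ] <- Inf
    dd[, !free_j] <- Inf
    idx <- arrayInd(which.min(dd), dim(dd))
    est[r] <- idx[1]
    pla[r] <- idx[2]
    tv[r] <- d[idx[1], idx[2]]
    free_i[idx[1]] <- FALSE
    free_j[idx[2]] <- FALSE
  }
  data.frame(estimated = est, planted = pla, tv = tv)
}
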