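# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so library code never clobbers the user's random stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

assert_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

# Row-normalize a nonnegative matrix; all-zero rows map to the uniform vector.
row_normalize <- function(m, zero_to_uniform = TRUE) {
  rs <- rowSums(m)
  zero <- rs == 0
  rs[zero] <- 1
  out <- m / rs
  if (zero_to_uniform && any(zero)) {
    out[zero, ] <- 1 / ncol(m)
  }
  out
}

# Draw one row-stochastic matrix whose rows are symmetric-Dirichlet samples.
rdirichlet_rows <- function(n, alpha) {
  # alpha: vector of concentrations (recycled across rows)
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha, rate = 1),
              nrow = n, byrow = TRUE)
  # rgamma(shape ~ 0) can underflow to all-zero rows; resample those
  bad <- rowSums(g) == 0
  while (any(bad)) {
    g[bad, ] <- matrix(
      stats::rgamma(sum(bad) * length(alpha), shape = alpha, rate = 1),
      nrow = sum(bad), byrow = TRUE)
    bad <- rowSums(g) == 0
  }
  g / rowSums(g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
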