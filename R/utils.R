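# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library calls never perturb user RNG flow.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible child seed from a master seed and a stream of integer
# tags (fold index, wolf index, iteration, ...). A multiplicative-congruential
# mix keeps results in [1, 2^31 - 2] so they are valid R seeds on all platforms.
child_seed <- function(seed, ...) {
  tags <- c(...)
  s <- as.double(abs(as.integer(seed)) %% 2147483647)
  for (x in tags) {
    s <- (s * 69069 + as.double(abs(as.integer(x))) + 1) %% 2147483647
  }
  as.integer(s %% 2147483646 + 1)
}

# Moore-Penrose pseudoinverse via SVD; singular values below tol * max(d) are
# cut to zero so rank-deficient hidden-layer matrices are handled stably.
pinv <- function(A, tol = 1e-12) {
  A <- as.matrix(A)
  s <- svd(A)
  if (length(s$d) == 0L || max(s$d) == 0) {
    return(matrix(0, ncol(A), nrow(A)))
  }
  keep <- s$d > tol * max(s$d)
  if (!any(keep)) {
    return(matrix(0, ncol(A), nrow(A)))
  }
  s$v[, keep, drop = FALSE] %*% ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
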