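# Shared fixture builders — all data is generated in code at test time.

# Two well-separated spherical Gaussian clouds (class 0 near -1, class 1
# near +1 on every feature); margin controls the cluster tightness.
make_separable_table <- function(n_per_class = 15, n_features = 2,
                                 sd = 0.05, seed = 42) {
  set.seed(seed)
  X0 <- matrix(stats::rnorm(n_per_class * n_features, -1, sd),
               n_per_class, n_features)
  X1 <- matrix(stats::rnorm(n_per_class * n_features, 1, sd),
               n_per_class, n_features)
  feature_table(rbind(X0, X1), rep(c(0L, 1L), each = n_per_class))
}

# Write a small CSV fixture and return its path.
write_csv_fixture <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Independent re-implementation of the confusion-count metrics used as the
# brute-force oracle (same degenerate-marginal conventions, different code).
oracle_metrics <- function(TP, FP, TN, FN) {
  tot <- TP + FP + TN + FN
  marg <- c(TP + FP, TP + FN, TN + FP, TN + FN)
  list(
    acc = (TP + TN) / tot,
    sens = if (TP + FN == 0) NaN else TP / (TP + FN),
    spec = if (TN + FP == 0) NaN else TN / (TN + FP),
    mcc = if (any(marg == 0)) 0 else {
      (TP * TN - FP * FN) / exp(0.5 * sum(log(marg)))
    }
  )
}

# Exhaustive positive-negative pair-counting AUC oracle (ties count 1/2).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) for (n in neg) {
    wins <- wins + (p > n) + 0.5 * (p == n)
  }
  wins / (length(pos) * length(neg))
}

# Recompute an ELM's hidden-layer matrix from its stored weights —
# independent of the package's internal helper.
oracle_hidden <- function(model, X) {
  Z <- X %*% t(model$W) + matrix(model$b, nrow(X), model$n_hidden, byrow = TRUE)
  switch(model$activation,
    sigmoid = 1 / (1 + exp(-Z)),
    tanh = tanh(Z),
    relu = pmax(Z, 0)
  )
}

one_hot_targets <- function(y) cbind(as.numeric(y == 0), as.numeric(y == 1))

# Seed-scoped evaluation that restores the session RNG state afterwards.
with_seed_local <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}
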