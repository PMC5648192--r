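#' Stratified k-fold assignments
#'
#' Deterministic given `seed`. Within each class the (shuffled) members are
#' dealt round-robin; the deal offset rotates between classes so fold sizes
#' stay balanced. Per-fold class counts differ from perfect proportionality by
#' at most one.
#'
#' @param y Binary label vector (`0`/`1`).
#' @param k Number of folds (`>= 2`). If a class has fewer than `k` members,
#'   `k` is reduced to the smallest class size with a warning.
#' @param seed Integer seed.
#' @return An object of class `fold_plan`: list with `k`, `assignments`
#'   (fold index per patient) and `seed`.
#' @examples
#' fp <- stratified_folds(rep(c(0, 1), c(51, 52)), k = 10, seed = 1)
#' table(fp$assignments)
#' @export
stratified_folds <- function(y, k, seed = 1L) {
  y <- as.integer(y)
  stopifnot(all(y %in% c(0L, 1L)))
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop("k must be at least 2")
  if (length(y) < 2L) stop("need at least 2 observations")
  if (k > length(y)) {
    warning("k reduced from ", k, " to ", length(y), " (sample size)")
    k <- length(y)
  }
  min_class <- min(table(factor(y, levels = c(0L, 1L))))
  if (min_class < k) {
    warning("smallest class has ", min_class, " member(s) < k = ", k,
            "; some folds will lack that class")
  }
  assignments <- integer(length(y))
  with_seed(seed, {
    offset <- 0L
    for (cls in c(1L, 0L)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      assignments[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      offset <- (offset + length(idx)) %% k
    }
  })
  structure(list(k = k, assignments = assignments, seed = as.integer(seed)),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> k = %d, n = %d, seed = %d\n",
              x$k, length(x$assignments), x$seed))
  print(table(fold = x$assignments))
  invisible(x)
}
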