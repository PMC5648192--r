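#' Per-feature two-group comparison
#'
#' For every feature, the group means and standard deviations (survival vs
#' deceased) and a two-sided independent two-sample t-test p-value. Welch's
#' unequal-variance test is the default — safer when group SDs differ wildly;
#' `var_equal = TRUE` gives the pooled-variance Student's t. A feature with
#' zero variance in both groups has an undefined test and reports `NA`.
#'
#' @param table A [feature_table()].
#' @param var_equal Pooled-variance Student's t instead of Welch.
#' @return A data frame of class `group_comparison`: `feature`,
#'   `mean_survival`, `sd_survival`, `mean_deceased`, `sd_deceased`,
#'   `p_value`, plus a formatted `p_display` column (`"<0.001"` below the
#'   display threshold).
#' @export
group_compare <- function(table, var_equal = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  g0 <- table$y == 0L
  g1 <- table$y == 1L
  if (!any(g0) || !any(g1)) stop("both groups must be non-empty")
  rows <- lapply(seq_len(ncol(table$X)), function(j) {
    a <- table$X[g0, j]
    b <- table$X[g1, j]
    p <- tryCatch(
      stats::t.test(a, b, var.equal = var_equal)$p.value,
      error = function(e) NA_real_
    )
    data.frame(
      feature = table$feature_names[j],
      mean_survival = mean(a), sd_survival = stats::sd(a),
      mean_deceased = mean(b), sd_deceased = stats::sd(b),
      p_value = p,
      p_display = if (is.na(p)) "NA" else if (p < 0.001) "<0.001" else sprintf("%.3f", p),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("group_comparison", class(out))
  out
}

#' ROC area under the curve with Hanley-McNeil confidence interval
#'
#' AUC by the Mann-Whitney pair-counting equivalence: the probability that a
#' random positive (deceased) outscores a random negative, ties counted 1/2,
#' computed via midranks. Orientation is fixed — higher score predicts class
#' 1 — and never auto-flipped, so an inversely related marker reports
#' AUC < 0.5 as-is. The 95% CI uses the Hanley-McNeil standard error with a
#' normal approximation; the p-value tests AUC = 0.5 two-sidedly with the
#' same standard error.
#'
#' @param scores Numeric marker values.
#' @param labels Binary labels (`1` = deceased/positive).
#' @param conf_level Confidence level, default 0.95.
#' @return An object of class `roc_result`: list with `auc`, `ci_lower`,
#'   `ci_upper`, `se`, `p_value`, `n_pos`, `n_neg`.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2), c(1, 1, 1, 0, 0, 0))
#' @export
roc_auc <- function(scores, labels, conf_level = 0.95) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  r <- rank(scores) # midranks handle ties as 1/2 wins
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- if (se > 0) 2 * stats::pnorm(-abs(auc - 0.5) / se) else
    as.numeric(auc == 0.5)
  structure(
    list(auc = auc, ci_lower = auc - z * se, ci_upper = auc + z * se,
         se = se, p_value = p, n_pos = n_pos, n_neg = n_neg),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f (95%% CI %.3f-%.3f), p = %s\n",
              x$auc, x$ci_lower, x$ci_upper,
              if (x$p_value < 0.001) "<0.001" else sprintf("%.3f", x$p_value)))
  invisible(x)
}

#' ROC coordinates for external plotting
#'
#' @param scores,labels As in [roc_auc()].
#' @return Data frame of `(fpr, tpr)` pairs over all score thresholds.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  do.call(rbind, lapply(thr, function(t) {
    pred <- as.integer(scores >= t)
    data.frame(
      threshold = t,
      fpr = sum(pred == 1L & labels == 0L) / max(sum(labels == 0L), 1L),
      tpr = sum(pred == 1L & labels == 1L) / max(sum(labels == 1L), 1L)
    )
  }))
}

#' ROC table for every feature of a table
#'
#' @param table A [feature_table()].
#' @return Data frame with one row per feature: `feature`, `auc`,
#'   `ci_lower`, `ci_upper`, `p_value`.
#' @export
roc_table <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  do.call(rbind, lapply(seq_len(ncol(table$X)), function(j) {
    r <- roc_auc(table$X[, j], table$y)
    data.frame(feature = table$feature_names[j], auc = r$auc,
               ci_lower = r$ci_lower, ci_upper = r$ci_upper,
               p_value = r$p_value, stringsAsFactors = FALSE)
  }))
}

#' Two-class Fisher linear discriminant
#'
#' Projects onto `w = Sw^-1 (m1 - m0)` (pooled within-group covariance) and
#' classifies at the midpoint of the projected group means; reports the
#' resubstitution accuracy on the original grouped cases. A singular pooled
#' covariance is ridge-regularized with a warning when
#' `regularize = TRUE` (default), otherwise it is an error.
#'
#' @param table A [feature_table()].
#' @param regularize Add a small ridge to a singular pooled covariance.
#' @return An object of class `fisher_lda`: list with `coefficients`,
#'   `threshold`, `accuracy`, `predictions`, `scores`.
#' @export
fisher_lda <- function(table, regularize = TRUE) {
  stopifnot(inherits(table, "feature_table"))
  g0 <- table$y == 0L
  g1 <- table$y == 1L
  if (sum(g0) < 2L || sum(g1) < 2L) stop("each group needs at least 2 members")
  X0 <- table$X[g0, , drop = FALSE]
  X1 <- table$X[g1, , drop = FALSE]
  m0 <- colMeans(X0)
  m1 <- colMeans(X1)
  n0 <- nrow(X0)
  n1 <- nrow(X1)
  Sw <- ((n0 - 1) * stats::cov(X0) + (n1 - 1) * stats::cov(X1)) / (n0 + n1 - 2)
  w <- tryCatch(
    solve(Sw, m1 - m0),
    error = function(e) {
      if (!regularize) {
        stop("pooled within-group covariance is singular; ",
             "drop collinear features or set regularize = TRUE")
      }
      warning("singular pooled covariance; ridge regularization applied")
      eps <- 1e-8 * mean(diag(Sw)) + 1e-12
      solve(Sw + diag(eps, ncol(Sw)), m1 - m0)
    }
  )
  scores <- drop(table$X %*% w)
  threshold <- sum(w * (m0 + m1)) / 2
  predictions <- as.integer(scores > threshold)
  structure(
    list(coefficients = stats::setNames(w, table$feature_names),
         threshold = threshold,
         accuracy = mean(predictions == table$y),
         predictions = predictions, scores = scores),
    class = "fisher_lda"
  )
}

#' @export
print.fisher_lda <- function(x, ...) {
  cat(sprintf("<fisher_lda> %.1f%% of original grouped cases correctly classified\n",
              100 * x$accuracy))
  invisible(x)
}
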