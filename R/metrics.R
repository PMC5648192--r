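#' Confusion counts for a two-class prediction
#'
#' The positive class is `1` (deceased): `TP` counts true = 1 and
#' predicted = 1, `TN` true = 0 and predicted = 0, `FP` true = 0 predicted 1,
#' `FN` true = 1 predicted 0.
#'
#' @param y_true,y_pred Equal-length 0/1 vectors.
#' @return An object of class `confusion_counts` with integer fields
#'   `TP`, `FP`, `TN`, `FN`.
#' @examples
#' confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusion_counts <- function(y_true, y_pred) {
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length")
  }
  stopifnot(all(y_true %in% c(0L, 1L)), all(y_pred %in% c(0L, 1L)))
  structure(
    list(
      TP = sum(y_true == 1L & y_pred == 1L),
      FP = sum(y_true == 0L & y_pred == 1L),
      TN = sum(y_true == 0L & y_pred == 0L),
      FN = sum(y_true == 1L & y_pred == 0L)
    ),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d FP=%d TN=%d FN=%d\n",
              x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Accuracy, MCC, sensitivity and specificity from confusion counts
#'
#' ACC = (TP+TN)/total; sensitivity = TP/(TP+FN) on the deceased class;
#' specificity = TN/(TN+FP) on the survival class;
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), reported on
#' the [-1, 1] scale. A zero MCC denominator (degenerate marginal) yields 0
#' with a warning; an empty positive or negative class yields `NaN`
#' sensitivity/specificity with a warning (excluded from fold averages).
#'
#' @param counts A [confusion_counts()] object, or a list with fields
#'   `TP`, `FP`, `TN`, `FN`.
#' @return An object of class `metric_set`: list with `acc`, `mcc`,
#'   `sensitivity`, `specificity`.
#' @examples
#' metric_set(confusion_counts(c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0),
#'                             c(1, 1, 1, 0, 1, 1, 0, 0, 0, 0)))
#' @export
metric_set <- function(counts) {
  TP <- as.double(counts$TP)
  FP <- as.double(counts$FP)
  TN <- as.double(counts$TN)
  FN <- as.double(counts$FN)
  total <- TP + FP + TN + FN
  if (total < 1) stop("metric evaluation needs at least one prediction")
  acc <- (TP + TN) / total
  if (TP + FN > 0) {
    sens <- TP / (TP + FN)
  } else {
    warning("no positive (deceased) cases; sensitivity is NaN")
    sens <- NaN
  }
  if (TN + FP > 0) {
    spec <- TN / (TN + FP)
  } else {
    warning("no negative (survival) cases; specificity is NaN")
    spec <- NaN
  }
  denom2 <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  if (denom2 > 0) {
    mcc <- (TP * TN - FP * FN) / sqrt(denom2)
  } else {
    warning("degenerate confusion marginal; MCC defined as 0")
    mcc <- 0
  }
  structure(
    list(acc = acc, mcc = mcc, sensitivity = sens, specificity = spec),
    class = "metric_set"
  )
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("<metric_set> ACC=%.4f MCC=%.4f sens=%.4f spec=%.4f\n",
              x$acc, x$mcc, x$sensitivity, x$specificity))
  invisible(x)
}

#' Mean and standard deviation of per-fold metrics
#'
#' Arithmetic mean and sample standard deviation per metric across CV folds.
#' `NaN` entries (empty-class folds) are excluded with a warning; a single
#' fold reports a standard deviation of 0 by convention.
#'
#' @param per_fold Non-empty list of [metric_set()] objects.
#' @return A data frame with one row per metric (`acc`, `mcc`, `sensitivity`,
#'   `specificity`) and columns `mean`, `sd`, `n`.
#' @export
aggregate_folds <- function(per_fold) {
  if (length(per_fold) < 1L) stop("need at least one fold")
  metrics <- c("acc", "mcc", "sensitivity", "specificity")
  rows <- lapply(metrics, function(m) {
    v <- vapply(per_fold, function(f) as.double(f[[m]]), numeric(1))
    bad <- is.nan(v) | is.na(v)
    if (any(bad)) {
      warning(sum(bad), " fold(s) excluded from the ", m, " average (NaN)")
      v <- v[!bad]
    }
    if (length(v) == 0L) {
      data.frame(metric = m, mean = NaN, sd = NaN, n = 0L)
    } else {
      data.frame(
        metric = m, mean = mean(v),
        sd = if (length(v) > 1L) stats::sd(v) else 0,
        n = length(v)
      )
    }
  })
  do.call(rbind, rows)
}
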