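#' Fitness configuration for wrapper feature selection
#'
#' The composite fitness is `f = w1 * f1 + w2 * f2`, where `f1` is the mean
#' inner-CV classification accuracy of the ELM on the masked features and
#' `f2 = 1 - selected/total` rewards parsimony. The weights must be
#' non-negative and sum to 1; the defaults (0.95 / 0.05) let accuracy
#' dominate with parsimony as tie-breaker.
#'
#' @param w1 Accuracy weight (default 0.95).
#' @param w2 Parsimony weight (default 0.05).
#' @param inner_k Inner CV fold count (default 5).
#' @param model An [elm_config()] for the inner classifiers.
#' @param frozen_elm If `TRUE`, every fitness evaluation reuses one fixed
#'   hidden-layer draw; if `FALSE` (default) each evaluation derives a child
#'   seed from the evaluation's agent/iteration, favoring robustness of the
#'   selected subset over exact refitting.
#' @return An object of class `fitness_config`.
#' @export
fitness_config <- function(w1 = 0.95, w2 = 0.05, inner_k = 5L,
                           model = elm_config(), frozen_elm = FALSE) {
  if (w1 < 0 || w2 < 0) stop("fitness weights must be non-negative")
  if (abs(w1 + w2 - 1) > 1e-8) stop("fitness weights must sum to 1")
  inner_k <- as.integer(inner_k)
  if (is.na(inner_k) || inner_k < 2L) stop("inner_k must be at least 2")
  stopifnot(inherits(model, "elm_config"))
  structure(
    list(w1 = w1, w2 = w2, inner_k = inner_k, model = model,
         frozen_elm = isTRUE(frozen_elm)),
    class = "fitness_config"
  )
}

#' Composite fitness of one feature mask
#'
#' Restricts the training columns to the mask, runs a stratified inner
#' `inner_k`-fold CV (train an ELM on the other folds, score accuracy on the
#' held-out fold), and combines mean accuracy with the parsimony term.
#' The empty mask is defined to have fitness 0 (worst) so the search
#' survives all-zero binarizations.
#'
#' @param mask 0/1 integer mask, one flag per column of `Xtrain`.
#' @param Xtrain Scaled numeric training matrix.
#' @param ytrain Binary labels.
#' @param config A [fitness_config()].
#' @param seed Integer seed for the inner folds and inner ELM draws;
#'   deterministic given `(mask, data, config, seed)`.
#' @return A fitness-value list: `f`, `f1` (mean inner-CV accuracy), `f2`,
#'   `selected_count`, `empty` flag.
#' @export
fitness_eval <- function(mask, Xtrain, ytrain, config = fitness_config(),
                         seed = 1L) {
  stopifnot(inherits(config, "fitness_config"))
  mask <- as.integer(mask)
  Xtrain <- as.matrix(Xtrain)
  if (length(mask) != ncol(Xtrain)) {
    stop("mask length does not match the number of features")
  }
  n <- length(mask)
  f2 <- 1 - sum(mask) / n
  if (sum(mask) == 0L) {
    return(list(f = 0, f1 = NA_real_, f2 = f2, selected_count = 0L,
                empty = TRUE))
  }
  sel <- which(mask == 1L)
  Xm <- Xtrain[, sel, drop = FALSE]
  folds <- suppressWarnings(stratified_folds(ytrain, config$inner_k, seed = seed))
  accs <- rep(NA_real_, folds$k)
  for (j in seq_len(folds$k)) {
    tr <- folds$assignments != j
    if (length(unique(ytrain[tr])) < 2L) {
      warning("inner fold ", j, " skipped: single-class training split")
      next
    }
    m <- elm_train(Xm[tr, , drop = FALSE], ytrain[tr], config$model,
                   seed = child_seed(seed, j))
    pred <- predict(m, Xm[!tr, , drop = FALSE])
    accs[j] <- mean(pred == ytrain[!tr])
  }
  f1 <- mean(accs, na.rm = TRUE)
  list(f = config$w1 * f1 + config$w2 * f2, f1 = f1, f2 = f2,
       selected_count = sum(mask), empty = FALSE)
}

#' Wrapper feature selection on a training set
#'
#' Wraps the ELM inner-CV fitness in the configured metaheuristic and
#' returns the best mask found (the alpha wolf for GWO). Operates on the
#' training portion only — it never sees held-out evaluation data.
#'
#' @param Xtrain Scaled numeric training matrix.
#' @param ytrain Binary labels.
#' @param opt_config An [optimizer_config()].
#' @param fit_config A [fitness_config()].
#' @return A list with `mask`, `fitness`, `history`, `n_evals`, `algorithm`.
#' @export
select_features <- function(Xtrain, ytrain, opt_config = optimizer_config(),
                            fit_config = fitness_config()) {
  Xtrain <- as.matrix(Xtrain)
  frozen <- child_seed(opt_config$seed, 999983L)
  fitness_fn <- function(mask, info) {
    s <- if (fit_config$frozen_elm) {
      frozen
    } else {
      child_seed(opt_config$seed, info$iter, info$agent)
    }
    fitness_eval(mask, Xtrain, ytrain, fit_config, seed = s)
  }
  optimize_mask(fitness_fn, ncol(Xtrain), opt_config)
}

#' Nested cross-validated evaluation of wrapper feature selection
#'
#' The full pipeline: stratified `outer_k`-fold split; per outer fold, run
#' [select_features()] on the training 9/10, train one final ELM on those
#' training rows restricted to the selected mask, and score it on the
#' held-out 1/10. Metrics are aggregated across folds and per-feature
#' selection frequencies tabulated.
#'
#' By default the feature scaler is fitted on each outer-training portion
#' and applied to its test portion (no information leak);
#' `scaling = "global"` reproduces the historically common — but leaky —
#' practice of scaling the full dataset once before CV.
#'
#' @param table A [feature_table()].
#' @param opt_config An [optimizer_config()] (its `seed` is re-derived per
#'   outer fold from `seed`).
#' @param fit_config A [fitness_config()].
#' @param outer_k Outer fold count, default 10.
#' @param seed Master seed for the outer folds and all per-fold searches.
#' @param scaling `"per_fold"` (default) or `"global"`.
#' @return An object of class `selection_report`: list with `per_fold`
#'   (each: `features`, `mask`, `metrics`, `fitness`, `history`), `summary`
#'   (from [aggregate_folds()]), `frequency` (named integer vector of
#'   selection counts), `fold_plan`, `feature_names`, `algorithm`, `config`.
#' @export
nested_evaluate <- function(table, opt_config = optimizer_config(),
                            fit_config = fitness_config(), outer_k = 10L,
                            seed = 1L, scaling = c("per_fold", "global")) {
  stopifnot(inherits(table, "feature_table"))
  scaling <- match.arg(scaling)
  folds <- stratified_folds(table$y, outer_k, seed = seed)
  X <- table$X
  if (scaling == "global") {
    X <- apply_scaler(suppressWarnings(fit_scaler(X)), X)
  }
  per_fold <- vector("list", folds$k)
  for (j in seq_len(folds$k)) {
    tr <- folds$assignments != j
    if (scaling == "per_fold") {
      sp <- suppressWarnings(fit_scaler(table$X[tr, , drop = FALSE]))
      Xtr <- apply_scaler(sp, table$X[tr, , drop = FALSE])
      Xte <- apply_scaler(sp, table$X[!tr, , drop = FALSE])
    } else {
      Xtr <- X[tr, , drop = FALSE]
      Xte <- X[!tr, , drop = FALSE]
    }
    oc <- opt_config
    oc$seed <- child_seed(seed, j)
    sf <- select_features(Xtr, table$y[tr], oc, fit_config)
    mask <- sf$mask
    if (sum(mask) == 0L) {
      warning("outer fold ", j, " selected an empty mask; falling back to all features")
      mask <- rep(1L, ncol(Xtr))
    }
    sel <- which(mask == 1L)
    model <- elm_train(Xtr[, sel, drop = FALSE], table$y[tr],
                       fit_config$model, seed = child_seed(seed, j, 777L))
    pred <- predict(model, Xte[, sel, drop = FALSE])
    ms <- suppressWarnings(metric_set(confusion_counts(table$y[!tr], pred)))
    per_fold[[j]] <- list(
      fold = j,
      features = table$feature_names[sel],
      mask = mask,
      metrics = ms,
      fitness = sf$fitness,
      history = sf$history
    )
  }
  masks <- do.call(rbind, lapply(per_fold, `[[`, "mask"))
  frequency <- stats::setNames(as.integer(colSums(masks)), table$feature_names)
  structure(
    list(
      per_fold = per_fold,
      summary = suppressWarnings(aggregate_folds(lapply(per_fold, `[[`, "metrics"))),
      frequency = frequency,
      fold_plan = folds,
      feature_names = table$feature_names,
      algorithm = opt_config$algorithm,
      config = list(optimizer = opt_config, fitness = fit_config,
                    outer_k = folds$k, seed = as.integer(seed),
                    scaling = scaling)
    ),
    class = "selection_report"
  )
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> %s, %d outer folds, seed %d\n",
              x$algorithm, length(x$per_fold), x$config$seed))
  print(x$summary, row.names = FALSE)
  top <- sort(x$frequency, decreasing = TRUE)
  top <- top[top > 0]
  cat("most selected:",
      paste(sprintf("%s(%d)", names(top)[seq_len(min(6, length(top)))],
                    top[seq_len(min(6, length(top)))]), collapse = " "), "\n")
  invisible(x)
}

#' Per-feature selection frequencies across reports
#'
#' Tabulates, per algorithm, how often each feature was selected across the
#' outer folds of one or more [nested_evaluate()] reports. All reports must
#' share the same feature-name universe.
#'
#' @param ... One or more `selection_report` objects (optionally named), or a
#'   single list of them.
#' @return A data frame: `feature` column plus one integer count column per
#'   report (named by the report's algorithm or the supplied name).
#' @export
feature_frequency <- function(...) {
  reports <- list(...)
  if (length(reports) == 1L && !inherits(reports[[1L]], "selection_report")) {
    reports <- reports[[1L]]
  }
  stopifnot(length(reports) >= 1L)
  features <- reports[[1L]]$feature_names
  out <- data.frame(feature = features, stringsAsFactors = FALSE)
  nms <- names(reports)
  for (i in seq_along(reports)) {
    r <- reports[[i]]
    stopifnot(inherits(r, "selection_report"))
    if (!identical(r$feature_names, features)) {
      stop("reports do not share a feature-name universe")
    }
    col <- if (!is.null(nms) && nzchar(nms[i] %||% "")) nms[i] else r$algorithm
    if (col %in% names(out)) col <- paste0(col, ".", i)
    out[[col]] <- as.integer(r$frequency)
  }
  out
}

#' Write a selection report as TSV and JSON artifacts
#'
#' Emits `folds.tsv` (fold, ACC, MCC, sensitivity, specificity,
#' selected_features), `summary.tsv`, `frequency.tsv`, one convergence TSV
#' per outer fold, and `report.json` with the resolved configuration.
#'
#' @param report A `selection_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "selection_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  folds_df <- do.call(rbind, lapply(report$per_fold, function(pf) {
    data.frame(
      fold = pf$fold, ACC = pf$metrics$acc, MCC = pf$metrics$mcc,
      sensitivity = pf$metrics$sensitivity,
      specificity = pf$metrics$specificity,
      selected_features = paste(pf$features, collapse = ";")
    )
  }))
  utils::write.table(folds_df, file.path(dir, "folds.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(report$summary, file.path(dir, "summary.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(feature = names(report$frequency),
               frequency = as.integer(report$frequency)),
    file.path(dir, "frequency.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  for (pf in report$per_fold) {
    utils::write.table(pf$history,
      file.path(dir, sprintf("convergence_fold%02d.tsv", pf$fold)),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }
  js <- list(
    algorithm = report$algorithm,
    outer_k = report$config$outer_k,
    seed = report$config$seed,
    scaling = report$config$scaling,
    weights = list(w1 = report$config$fitness$w1, w2 = report$config$fitness$w2),
    model = list(n_hidden = report$config$fitness$model$n_hidden,
                 activation = report$config$fitness$model$activation),
    optimizer = list(pop_size = report$config$optimizer$pop_size,
                     max_iters = report$config$optimizer$max_iters),
    summary = report$summary,
    frequency = as.list(report$frequency),
    per_fold = lapply(report$per_fold, function(pf) {
      list(fold = pf$fold, features = pf$features,
           acc = pf$metrics$acc, mcc = pf$metrics$mcc,
           sensitivity = pf$metrics$sensitivity,
           specificity = pf$metrics$specificity)
    })
  )
  jsonlite::write_json(js, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
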