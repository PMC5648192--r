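#' Extreme learning machine configuration
#'
#' Defaults follow the tuned model used throughout the package: 45 hidden
#' neurons with a sigmoid activation, one-hot target encoding.
#'
#' @param n_hidden Number of hidden neurons (`>= 1`), default 45.
#' @param activation Hidden activation: `"sigmoid"` (default), `"tanh"` or
#'   `"relu"`.
#' @param target_encoding `"one_hot"` (two output columns with 1/0 targets,
#'   arg-max decision; default) or `"signed_scalar"` (single column with
#'   -1/+1 targets, sign decision).
#' @return An object of class `elm_config`.
#' @export
elm_config <- function(n_hidden = 45L,
                       activation = c("sigmoid", "tanh", "relu"),
                       target_encoding = c("one_hot", "signed_scalar")) {
  n_hidden <- as.integer(n_hidden)
  if (is.na(n_hidden) || n_hidden < 1L) stop("n_hidden must be a positive integer")
  structure(
    list(n_hidden = n_hidden, activation = match.arg(activation),
         target_encoding = match.arg(target_encoding)),
    class = "elm_config"
  )
}

activation_fn <- function(name) {
  switch(name,
    sigmoid = function(z) 1 / (1 + exp(-z)),
    tanh = tanh,
    relu = function(z) pmax(z, 0),
    stop("unknown activation: ", name)
  )
}

hidden_layer <- function(X, W, b, activation) {
  Z <- tcrossprod(X, W)
  Z <- sweep(Z, 2L, b, "+")
  activation_fn(activation)(Z)
}

#' Train an extreme learning machine
#'
#' Input weights `W` and hidden biases `b` are drawn once, uniformly on
#' `[-1, 1]` (W first, then b), and never adjusted. Output weights `beta` are
#' the minimum-norm least-squares solution `pinv(H) %*% T`, where `H` is the
#' hidden-layer output matrix, computed via an SVD pseudoinverse with singular
#' values below `1e-12 * max` cut to zero.
#'
#' @param X Numeric training matrix (ideally pre-scaled to `[-1, 1]`).
#' @param y Binary labels (`1` = deceased, `0` = survival).
#' @param config An [elm_config()].
#' @param seed Integer seed for the random hidden layer; the same
#'   `(X, y, config, seed)` yields bitwise-identical weights.
#' @return An object of class `elm_model` with fields `W`, `b`, `beta`,
#'   `n_hidden`, `activation`, `target_encoding`, `n_features`, `seed`.
#' @examples
#' X <- matrix(c(-1, -1, -1, 1, 1, -1, 1, 1), 4, 2, byrow = TRUE)
#' y <- c(0, 0, 1, 1)
#' m <- elm_train(X, y, elm_config(n_hidden = 20), seed = 1)
#' predict(m, X)
#' @export
elm_train <- function(X, y, config = elm_config(), seed = 1L) {
  stopifnot(inherits(config, "elm_config"))
  X <- as.matrix(X)
  y <- as.integer(y)
  if (nrow(X) < 1L) stop("empty training matrix")
  if (length(y) != nrow(X)) stop("label length does not match rows")
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1")
  if (length(unique(y)) < 2L) {
    warning("training labels contain a single class; the model will predict it everywhere")
  }
  L <- config$n_hidden
  p <- ncol(X)
  draws <- with_seed(seed, stats::runif(L * p + L, min = -1, max = 1))
  W <- matrix(draws[seq_len(L * p)], nrow = L, ncol = p)
  b <- draws[L * p + seq_len(L)]
  H <- hidden_layer(X, W, b, config$activation)
  Tm <- if (config$target_encoding == "one_hot") {
    cbind(survival = as.numeric(y == 0L), deceased = as.numeric(y == 1L))
  } else {
    matrix(2 * y - 1, ncol = 1L)
  }
  beta <- pinv(H) %*% Tm
  structure(
    list(n_hidden = L, W = W, b = b, beta = beta,
         activation = config$activation,
         target_encoding = config$target_encoding,
         n_features = p, seed = as.integer(seed)),
    class = "elm_model"
  )
}

#' Predict class labels or scores from an ELM
#'
#' One-hot models predict by arg-max over the two output columns; ties go to
#' class 0 (survival) by fixed rule. Signed-scalar models threshold the score
#' at 0, with 0 itself mapping to class 0.
#'
#' @param object An `elm_model`.
#' @param X Matrix with `object$n_features` columns (scaled like the training
#'   data). Zero rows yield a zero-length result.
#' @param type `"class"` (default) for 0/1 labels or `"score"` for the raw
#'   output matrix.
#' @param ... Unused.
#' @return Integer label vector, or the score matrix when `type = "score"`.
#' @export
predict.elm_model <- function(object, X, type = c("class", "score"), ...) {
  type <- match.arg(type)
  X <- as.matrix(X)
  if (ncol(X) != object$n_features) {
    stop("dimension mismatch: model expects ", object$n_features,
         " features, input has ", ncol(X))
  }
  if (nrow(X) == 0L) {
    return(if (type == "class") integer(0) else
      matrix(numeric(0), 0L, ncol(object$beta)))
  }
  H <- hidden_layer(X, object$W, object$b, object$activation)
  S <- H %*% object$beta
  if (type == "score") return(S)
  if (object$target_encoding == "one_hot") {
    as.integer(S[, 2L] > S[, 1L])
  } else {
    as.integer(S[, 1L] > 0)
  }
}

#' @rdname predict.elm_model
#' @param model An `elm_model`.
#' @export
elm_predict <- function(model, X, type = c("class", "score")) {
  predict(model, X, type = match.arg(type))
}

#' @export
print.elm_model <- function(x, ...) {
  cat(sprintf(
    "<elm_model> %d hidden neurons (%s), %d features, %s encoding, seed %d\n",
    x$n_hidden, x$activation, x$n_features, x$target_encoding, x$seed
  ))
  invisible(x)
}

#' Serialize / restore an ELM model as plain text
#'
#' A documented line-oriented format for audit: a header (format tag, sizes,
#' activation, encoding, seed) followed by the rows of `W`, then `b`, then the
#' rows of `beta`, all printed with 17 significant digits so the round trip is
#' exact in double precision.
#'
#' @param model An `elm_model`.
#' @param path Output (or input) file path.
#' @return `write_elm` invisibly returns `path`; `read_elm` returns the model.
#' @export
write_elm <- function(model, path) {
  stopifnot(inherits(model, "elm_model"))
  num <- function(v) paste(sprintf("%.17g", v), collapse = " ")
  lines <- c(
    "gwoelm-model 1",
    paste("n_hidden", model$n_hidden),
    paste("n_features", model$n_features),
    paste("n_outputs", ncol(model$beta)),
    paste("activation", model$activation),
    paste("target_encoding", model$target_encoding),
    paste("seed", model$seed),
    vapply(seq_len(nrow(model$W)), function(i) num(model$W[i, ]), ""),
    num(model$b),
    vapply(seq_len(nrow(model$beta)), function(i) num(model$beta[i, ]), "")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_elm
#' @export
read_elm <- function(path) {
  lines <- readLines(path)
  if (lines[1L] != "gwoelm-model 1") stop("not a gwoelm model file: ", path)
  kv <- strsplit(lines[2:7], " ", fixed = TRUE)
  hdr <- stats::setNames(
    vapply(kv, `[`, "", 2L),
    vapply(kv, `[`, "", 1L)
  )
  L <- as.integer(hdr[["n_hidden"]])
  p <- as.integer(hdr[["n_features"]])
  q <- as.integer(hdr[["n_outputs"]])
  row_at <- 7L
  parse_rows <- function(k, width) {
    m <- t(vapply(
      lines[row_at + seq_len(k)],
      function(ln) as.numeric(strsplit(ln, " ", fixed = TRUE)[[1L]]),
      numeric(width)
    ))
    row_at <<- row_at + k
    unname(m)
  }
  W <- parse_rows(L, p)
  b <- as.numeric(parse_rows(1L, L))
  beta <- parse_rows(L, q)
  if (hdr[["target_encoding"]] == "one_hot") {
    colnames(beta) <- c("survival", "deceased")
  }
  structure(
    list(n_hidden = L, W = W, b = b, beta = beta,
         activation = hdr[["activation"]],
         target_encoding = hdr[["target_encoding"]],
         n_features = p, seed = as.integer(hdr[["seed"]])),
    class = "elm_model"
  )
}

#' Cross-validated accuracy as a function of hidden-layer size
#'
#' For each candidate hidden-neuron count, runs a stratified k-fold CV of a
#' plain ELM (scaler fitted on each training fold) and records the mean test
#' accuracy — the standard sweep used to pick the hidden-layer size.
#'
#' @param table A [feature_table()].
#' @param n_hidden Integer vector of hidden-layer sizes to try (e.g. `1:100`).
#' @param k Fold count for the CV, default 10.
#' @param seed Integer seed (folds and per-fold hidden layers).
#' @param config Base [elm_config()]; its `n_hidden` is overridden per sweep
#'   point.
#' @return A data frame with columns `n_hidden` and `accuracy`.
#' @export
sweep_hidden_neurons <- function(table, n_hidden, k = 10L, seed = 1L,
                                 config = elm_config()) {
  stopifnot(inherits(table, "feature_table"), length(n_hidden) >= 1L)
  folds <- stratified_folds(table$y, k, seed = seed)
  acc <- vapply(as.integer(n_hidden), function(L) {
    cfg <- config
    cfg$n_hidden <- L
    fold_acc <- vapply(seq_len(folds$k), function(j) {
      tr <- folds$assignments != j
      sp <- suppressWarnings(fit_scaler(table$X[tr, , drop = FALSE]))
      m <- elm_train(apply_scaler(sp, table$X[tr, , drop = FALSE]),
                     table$y[tr], cfg, seed = child_seed(seed, L, j))
      pred <- predict(m, apply_scaler(sp, table$X[!tr, , drop = FALSE]))
      mean(pred == table$y[!tr])
    }, numeric(1))
    mean(fold_acc)
  }, numeric(1))
  data.frame(n_hidden = as.integer(n_hidden), accuracy = acc)
}
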