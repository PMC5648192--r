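#' Fit a per-feature linear scaler
#'
#' Maps each feature's fitted minimum to the lower target endpoint and its
#' fitted maximum to the upper one (default `[-1, 1]`). Constant features are
#' flagged with a warning and mapped to the interval midpoint.
#'
#' @param x A [feature_table()] or numeric matrix.
#' @param range Target interval endpoints, default `c(-1, 1)`.
#' @return An object of class `scaling_spec` with per-feature `min`, `max`
#'   and the target `range`.
#' @examples
#' sp <- fit_scaler(matrix(c(0, 5, 10), ncol = 1))
#' apply_scaler(sp, matrix(c(0, 5, 10), ncol = 1))
#' @export
fit_scaler <- function(x, range = c(-1, 1)) {
  X <- if (inherits(x, "feature_table")) x$X else as.matrix(x)
  stopifnot(length(range) == 2L, range[2] > range[1])
  mins <- apply(X, 2L, min)
  maxs <- apply(X, 2L, max)
  const <- maxs <= mins
  if (any(const)) {
    warning(
      "constant feature(s) mapped to the interval midpoint: ",
      paste(colnames(X)[const] %||% which(const), collapse = ", ")
    )
  }
  structure(
    list(min = mins, max = maxs, range = as.numeric(range),
         feature_names = colnames(X)),
    class = "scaling_spec"
  )
}

#' Apply a fitted scaler to a matrix
#'
#' Values outside the fitted `[min, max]` (test data beyond the training
#' range) extrapolate linearly beyond the target endpoints without clipping.
#'
#' @param spec A `scaling_spec` from [fit_scaler()].
#' @param X Numeric matrix (or [feature_table()]) with the same column count
#'   as the fitting data.
#' @return A scaled numeric matrix.
#' @export
apply_scaler <- function(spec, X) {
  stopifnot(inherits(spec, "scaling_spec"))
  X <- if (inherits(X, "feature_table")) X$X else as.matrix(X)
  if (ncol(X) != length(spec$min)) {
    stop("dimension mismatch: scaler was fitted on ", length(spec$min),
         " features, input has ", ncol(X))
  }
  lo <- spec$range[1]
  hi <- spec$range[2]
  out <- X
  for (j in seq_len(ncol(X))) {
    span <- spec$max[j] - spec$min[j]
    if (span <= 0) {
      out[, j] <- (lo + hi) / 2
    } else {
      out[, j] <- lo + (X[, j] - spec$min[j]) / span * (hi - lo)
    }
  }
  out
}
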