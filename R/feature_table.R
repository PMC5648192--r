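#' Construct a validated patient feature table
#'
#' The universal input container: one row per patient, numeric laboratory
#' features in columns, and a binary outcome (`1` = deceased, `0` = survival).
#'
#' @param X Numeric matrix or data frame, patients in rows, features in columns.
#' @param y Binary outcome vector (`0`/`1`), one entry per row of `X`.
#' @param feature_names Character vector of unique feature names; defaults to
#'   the column names of `X`.
#' @param ids Optional patient identifiers (length `nrow(X)`).
#'
#' @return An object of class `feature_table`: a list with elements
#'   `X` (numeric matrix), `y` (integer vector), `feature_names`, `ids`.
#' @examples
#' ft <- feature_table(matrix(rnorm(20), 10, 2), rep(c(0, 1), 5))
#' ft$feature_names
#' @export
feature_table <- function(X, y, feature_names = colnames(X), ids = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) == 0L || ncol(X) < 1L) {
    stop("feature table needs at least one patient and one feature")
  }
  if (anyNA(X) || any(!is.finite(X))) {
    stop("feature matrix contains missing or non-finite values")
  }
  if (is.null(feature_names)) {
    feature_names <- paste0("F", seq_len(ncol(X)))
  }
  feature_names <- as.character(feature_names)
  if (length(feature_names) != ncol(X)) {
    stop("feature_names length does not match the number of columns")
  }
  if (anyDuplicated(feature_names)) {
    stop("feature names must be unique")
  }
  y <- as.integer(y)
  if (length(y) != nrow(X)) {
    stop("outcome length does not match the number of rows")
  }
  if (anyNA(y) || !all(y %in% c(0L, 1L))) {
    stop("outcome values must all be 0 (survival) or 1 (deceased)")
  }
  if (!is.null(ids) && length(ids) != nrow(X)) {
    stop("ids length does not match the number of rows")
  }
  colnames(X) <- feature_names
  structure(
    list(X = X, y = y, feature_names = feature_names, ids = ids),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "<feature_table> %d patients x %d features (deceased %d / survival %d)\n",
    nrow(x$X), ncol(x$X), sum(x$y == 1L), sum(x$y == 0L)
  ))
  cat("features:", paste(x$feature_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$X)

#' Read a patient feature table from delimited text
#'
#' Expects a header row, one binary outcome column (default name `"outcome"`)
#' and numeric feature columns. Feature names containing CSV metacharacters
#' (e.g. `ALT/AST`) are preserved verbatim.
#'
#' @param path Path to the file.
#' @param dialect `"csv"` (comma) or `"tsv"` (tab).
#' @param outcome_col Name of the outcome column.
#' @param missing How to handle rows with missing cells: `"reject"` (error,
#'   default) or `"impute_median"` (per-feature median imputation).
#'
#' @return A [feature_table()].
#' @export
load_table <- function(path, dialect = c("csv", "tsv"), outcome_col = "outcome",
                       missing = c("reject", "impute_median")) {
  dialect <- match.arg(dialect)
  missing <- match.arg(missing)
  if (!file.exists(path)) stop("input file not found: ", path)
  sep <- if (dialect == "csv") "," else "\t"
  raw <- utils::read.table(path,
    header = TRUE, sep = sep, quote = "\"",
    check.names = FALSE, colClasses = "character",
    stringsAsFactors = FALSE, comment.char = ""
  )
  if (!outcome_col %in% names(raw)) {
    stop("format error: no outcome column named '", outcome_col, "' in ", path)
  }
  ids <- NULL
  if ("id" %in% names(raw) && outcome_col != "id") {
    ids <- raw[["id"]]
    raw[["id"]] <- NULL
  }
  y_chr <- trimws(raw[[outcome_col]])
  raw[[outcome_col]] <- NULL
  y_num <- suppressWarnings(as.numeric(y_chr))
  if (anyNA(y_num) || !all(y_num %in% c(0, 1))) {
    bad <- which(is.na(y_num) | !(y_num %in% c(0, 1)))[1L]
    stop(
      "validation error: outcome value '", y_chr[bad],
      "' at row ", bad, " is not 0 or 1"
    )
  }
  n_feat <- ncol(raw)
  if (n_feat < 1L) stop("format error: no feature columns found")
  X <- matrix(NA_real_, nrow(raw), n_feat, dimnames = list(NULL, names(raw)))
  for (j in seq_len(n_feat)) {
    col <- trimws(raw[[j]])
    is_blank <- !nzchar(col) | toupper(col) %in% c("NA", "NAN")
    v <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(v) & !is_blank)
    if (length(bad)) {
      stop(
        "parse error: non-numeric cell '", col[bad[1L]], "' at row ", bad[1L],
        ", column '", names(raw)[j], "'"
      )
    }
    X[, j] <- v
  }
  if (anyNA(X)) {
    if (missing == "reject") {
      keep <- stats::complete.cases(X)
      stop(
        "validation error: ", sum(!keep),
        " row(s) contain missing cells (use missing = 'impute_median' to impute)"
      )
    }
    for (j in seq_len(ncol(X))) {
      nas <- is.na(X[, j])
      if (any(nas)) X[nas, j] <- stats::median(X[, j], na.rm = TRUE)
    }
  }
  feature_table(X, as.integer(y_num), feature_names = colnames(X), ids = ids)
}

#' Write a feature table to delimited text
#'
#' Round-trips with [load_table()] at full double precision.
#'
#' @param table A [feature_table()].
#' @param path Output path.
#' @param dialect `"csv"` or `"tsv"`.
#' @return Invisibly, `path`.
#' @export
write_table <- function(table, path, dialect = c("csv", "tsv")) {
  stopifnot(inherits(table, "feature_table"))
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  df <- as.data.frame(table$X, check.names = FALSE)
  df[["outcome"]] <- table$y
  if (!is.null(table$ids)) df <- cbind(id = table$ids, df)
  utils::write.table(df, path,
    sep = sep, row.names = FALSE,
    col.names = TRUE, quote = TRUE
  )
  invisible(path)
}

# Restrict a feature table to a subset of feature columns (internal).
subset_features <- function(table, keep) {
  feature_table(table$X[, keep, drop = FALSE], table$y,
    feature_names = table$feature_names[keep], ids = table$ids
  )
}
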