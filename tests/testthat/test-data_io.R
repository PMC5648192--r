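test_that("load_table parses, validates and preserves order", {
  path <- write_csv_fixture(c(
    '"PT","ALT/AST","outcome"',
    "15.1,1.2,1",
    "12.0,0.9,0",
    "17.3,0.5,1"
  ))
  ft <- load_table(path)
  expect_s3_class(ft, "feature_table")
  expect_equal(dim(ft), c(3L, 2L))
  expect_identical(ft$feature_names, c("PT", "ALT/AST"))
  expect_identical(ft$y, c(1L, 0L, 1L))
  expect_equal(ft$X[, "PT"], c(15.1, 12.0, 17.3))

  bad_outcome <- write_csv_fixture(c("a,outcome", "1,2", "2,0"))
  expect_error(load_table(bad_outcome), "validation error.*not 0 or 1")

  no_outcome <- write_csv_fixture(c("a,b", "1,2"))
  expect_error(load_table(no_outcome), "format error")

  bad_cell <- write_csv_fixture(c("a,outcome", "1,1", "oops,0"))
  expect_error(load_table(bad_cell), "parse error.*'oops'.*row 2.*'a'")
})

test_that("missing cells are rejected by default and imputable on request", {
  path <- write_csv_fixture(c("a,b,outcome", "1,2,1", ",4,0", "3,6,1"))
  expect_error(load_table(path), "missing cells")
  ft <- load_table(path, missing = "impute_median")
  expect_equal(unname(ft$X[2, "a"]), 2) # median of {1, 3}
})

test_that("write_table round-trips values at full precision", {
  set.seed(7)
  ft <- feature_table(matrix(stats::rnorm(12) * 1e3, 4, 3,
                             dimnames = list(NULL, c("PT", "ALT/AST", "Alb/Glo"))),
                      c(0, 1, 0, 1))
  for (dialect in c("csv", "tsv")) {
    path <- tempfile()
    write_table(ft, path, dialect = dialect)
    back <- load_table(path, dialect = dialect)
    expect_identical(back$feature_names, ft$feature_names)
    expect_identical(back$y, ft$y)
    expect_equal(back$X, ft$X, tolerance = 1e-14)
  }
})

test_that("feature_table enforces its invariants", {
  expect_error(feature_table(matrix(1:4, 2), c(0, 2)), "0.*or 1|0 \\(survival\\)")
  expect_error(feature_table(matrix(c(1, NA, 3, 4), 2), c(0, 1)), "missing")
  expect_error(
    feature_table(matrix(1:4, 2, dimnames = list(NULL, c("a", "a"))), c(0, 1)),
    "unique"
  )
})

test_that("fit_scaler maps fitted min/max to the interval endpoints", {
  sp <- fit_scaler(matrix(c(0, 5, 10), ncol = 1))
  expect_equal(drop(apply_scaler(sp, matrix(c(0, 5, 10), ncol = 1))),
               c(-1, 0, 1))
  # linear map: fitted on {2, 4}, unseen midpoint 3 lands at 0
  sp2 <- fit_scaler(matrix(c(2, 4), ncol = 1))
  expect_equal(drop(apply_scaler(sp2, matrix(3, 1, 1))), 0)
  # extrapolation beyond the fitted range is linear, not clipped
  sp3 <- fit_scaler(matrix(c(0, 10), ncol = 1))
  expect_equal(drop(apply_scaler(sp3, matrix(20, 1, 1))), 3)
  # identity interval
  sp4 <- fit_scaler(matrix(c(-1, 1), ncol = 1))
  expect_equal(drop(apply_scaler(sp4, matrix(c(-0.3, 0.7), 2, 1))), c(-0.3, 0.7))
})

test_that("constant features warn and scale to the midpoint", {
  expect_warning(sp <- fit_scaler(matrix(c(7, 7, 7), ncol = 1)), "constant")
  expect_equal(drop(apply_scaler(sp, matrix(c(7, 7), 2, 1))), c(0, 0))
})

test_that("scaling own fitting data always lands in [-1, 1] with endpoints attained", {
  set.seed(11)
  for (i in 1:20) {
    X <- matrix(stats::rnorm(40, sd = 10^stats::runif(1, -2, 3)), 10, 4)
    S <- apply_scaler(fit_scaler(X), X)
    expect_true(all(S >= -1 - 1e-12 & S <= 1 + 1e-12))
    expect_equal(unname(apply(S, 2, min)), rep(-1, 4))
    expect_equal(unname(apply(S, 2, max)), rep(1, 4))
  }
  expect_error(apply_scaler(fit_scaler(X), X[, 1:2]), "dimension mismatch")
})

test_that("stratified folds partition, stratify and reproduce", {
  y <- rep(c(1L, 0L), c(52L, 51L))
  fp <- stratified_folds(y, 10, seed = 5)
  sizes <- table(fp$assignments)
  expect_length(sizes, 10)
  expect_true(all(sizes %in% c(10, 11)))
  ones <- tapply(y, fp$assignments, sum)
  expect_true(all(ones %in% c(5, 6)))
  # partition: every patient in exactly one fold
  expect_equal(sum(sizes), length(y))
  # determinism
  expect_identical(stratified_folds(y, 10, seed = 5)$assignments, fp$assignments)
  expect_false(identical(stratified_folds(y, 10, seed = 6)$assignments,
                         fp$assignments))
})

test_that("fold stratification stays within one of proportionality", {
  set.seed(3)
  for (i in 1:15) {
    n1 <- sample(5:40, 1)
    n0 <- sample(5:40, 1)
    k <- sample(2:5, 1)
    y <- sample(rep(c(0L, 1L), c(n0, n1)))
    fp <- stratified_folds(y, k, seed = i)
    for (cls in 0:1) {
      per_fold <- tabulate(fp$assignments[y == cls], nbins = fp$k)
      expect_true(all(abs(per_fold - sum(y == cls) / fp$k) <= 1))
    }
  }
})

test_that("degenerate fold requests behave as documented", {
  y <- rep(c(0L, 1L), each = 3L)
  expect_error(stratified_folds(y, 1), "at least 2")
  # leave-one-out: k = n gives singleton folds (with a class-coverage warning)
  expect_warning(fp <- stratified_folds(y, 6, seed = 1), "lack")
  expect_true(all(table(fp$assignments) == 1))
})
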