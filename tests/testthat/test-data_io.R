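test_that("load_dataset parses a toy file and maps labels under the schema", {
  path <- write_toy_file(c("a,b,c,class",
                           "1,2,3,pos",
                           "4,5,6,pos",
                           "7,8,9,neg",
                           "1,1,1,neg"))
  ds <- load_dataset(path, toy_schema())
  expect_s3_class(ds, "fs_dataset")
  expect_equal(ds$n, 4L)
  expect_equal(ds$m, 3L)
  expect_equal(ds$y, c(1L, 1L, 0L, 0L))
  expect_equal(ds$feature_names, c("a", "b", "c"))
})

test_that("load_dataset rejects single-class files and absent label columns", {
  path <- write_toy_file(c("a,b,class", "1,2,pos", "3,4,pos"))
  expect_error(load_dataset(path, toy_schema()), "single-class")
  expect_error(
    load_dataset(path, dataset_schema(label_column = "nope",
                                      positive_label = "pos")),
    "absent")
})

test_that("missing markers become NA cells that are retained at load time", {
  path <- write_toy_file(c("a,b,class", "1,NA,pos", "?,4,neg", "5,6,pos",
                           "7,8,neg"))
  ds <- load_dataset(path, toy_schema())
  expect_equal(ds$n, 4L)
  expect_true(is.na(ds$x[1, 2]))
  expect_true(is.na(ds$x[2, 1]))
  expect_equal(sum(is.na(ds$x)), 2L)
})

test_that("schema round-trips through YAML and JSON config files", {
  ypath <- write_toy_file(c("label_column: class", "positive_label: pos",
                            "delimiter: ';'"), ext = ".yaml")
  sy <- read_schema(ypath)
  expect_equal(sy$label_column, "class")
  expect_equal(sy$delimiter, ";")

  jpath <- write_toy_file(
    '{"label_column": "y", "positive_label": 1, "missing_markers": ["?"]}',
    ext = ".json")
  sj <- read_schema(jpath)
  expect_equal(sj$label_column, "y")
  expect_equal(sj$missing_markers, "?")
})

test_that("clean_missing drops the worst-missing columns, then incomplete rows", {
  x <- matrix(rnorm(50), 10, 5)
  x[1:6, 2] <- NA   # worst column
  x[1:4, 4] <- NA   # second worst
  y <- rep(c(1L, 0L), 5)
  ds <- fs_dataset(x, y)

  # dropping the two heavy columns leaves complete rows: no row lost
  out <- clean_missing(ds, drop_worst_vars = 2L)
  expect_equal(out$m, 3L)
  expect_equal(out$n, 10L)
  expect_equal(out$feature_names, c("f1", "f3", "f5"))
  expect_false(anyNA(out$x))

  # no missing values and nothing to drop: identity
  ds2 <- fs_dataset(matrix(rnorm(20), 5, 4), c(1, 0, 1, 0, 1))
  out2 <- clean_missing(ds2, 0L)
  expect_equal(out2$x, ds2$x)

  # rows still incomplete after the column drop are removed
  x3 <- matrix(rnorm(25), 5, 5)
  x3[, 1] <- NA            # the dropped column
  x3[2, 3] <- NA           # survives the drop; kills row 2
  x3[4, 5] <- NA           # kills row 4
  ds3 <- fs_dataset(x3, c(1, 0, 0, 0, 1))
  out3 <- clean_missing(ds3, 1L)
  expect_equal(out3$n, 3L)
  expect_false(anyNA(out3$x))
})

test_that("clean_missing breaks missing-count ties toward the lower column index", {
  x <- matrix(rnorm(40), 10, 4)
  x[1:3, 2] <- NA
  x[4:6, 3] <- NA  # same count as column 2
  ds <- fs_dataset(x, rep(c(1L, 0L), 5))
  out <- clean_missing(ds, 1L)
  expect_equal(out$feature_names, c("f1", "f3", "f4"))  # f2 dropped, not f3
})

test_that("clean_missing errors when every case would be removed", {
  x <- matrix(NA_real_, 4, 2)
  ds <- fs_dataset(x, c(1, 0, 1, 0))
  expect_error(clean_missing(ds, 0L), "every case")
})

test_that("z-score normalization matches the closed form and handles constants", {
  train <- fs_dataset(cbind(a = c(1, 2, 3), b = c(5, 5, 5)),
                      c(1L, 0L, 1L))
  test <- fs_dataset(cbind(a = c(4, 2), b = c(7, 5)), c(1L, 0L))
  out <- normalize_features(train, list(test))

  # population sd of (1,2,3) is 0.8165; z-scores are +/- 1.2247
  expect_equal(round(out$train$x[, "a"], 4), c(-1.2247, 0, 1.2247),
               ignore_attr = TRUE)
  # constant training feature maps to all-zeros everywhere
  expect_equal(unname(out$train$x[, "b"]), c(0, 0, 0))
  expect_equal(unname(out$others[[1]]$x[, "b"]), c(0, 0))
  # test value transformed with train statistics: (4 - 2) / 0.8165 = 2.4495
  expect_equal(round(out$others[[1]]$x[1, "a"], 4), 2.4495, ignore_attr = TRUE)
})

test_that("z-score normalization is idempotent on its own output", {
  ds <- null_dataset(n = 60, m = 5, seed = 7)
  once <- normalize_features(ds)$train
  twice <- normalize_features(once)$train
  expect_lt(max(abs(once$x - twice$x)), 1e-9)
})

test_that("min-max normalization rescales to the training range", {
  train <- fs_dataset(cbind(a = c(0, 5, 10)), c(1L, 0L, 1L))
  test <- fs_dataset(cbind(a = c(2.5, 20)), c(1L, 0L))
  out <- normalize_features(train, list(test), method = "minmax")
  expect_equal(unname(out$train$x[, 1]), c(0, 0.5, 1))
  expect_equal(unname(out$others[[1]]$x[, 1]), c(0.25, 2))
})

test_that("stratified folds balance classes and partition the cases exactly", {
  # n = 10, balanced 5/5, k = 10: ten singleton folds
  y <- rep(c(1L, 0L), 5)
  plan <- stratified_kfold(y, k = 10, seed = 3)
  expect_equal(sort(unique(plan$assignments)), 1:10)
  expect_true(all(table(plan$assignments) == 1))

  # n = 20 with a 12/8 split, k = 4: every fold has 3 positives, 2 negatives
  y2 <- c(rep(1L, 12), rep(0L, 8))
  plan2 <- stratified_kfold(y2, k = 4, seed = 11)
  comp <- table(fold = plan2$assignments, class = y2)
  expect_true(all(comp[, "1"] == 3))
  expect_true(all(comp[, "0"] == 2))

  # union of test folds is exactly 1..n with no repeats
  tests <- unlist(lapply(1:4, function(i) fold_split(plan2, i)$test))
  expect_setequal(tests, seq_along(y2))
  expect_equal(length(tests), length(y2))
})

test_that("fold plans are deterministic per seed and vary across seeds", {
  y <- rep(c(1L, 0L), 25)
  p1 <- stratified_kfold(y, 5, seed = 42)
  p2 <- stratified_kfold(y, 5, seed = 42)
  p3 <- stratified_kfold(y, 5, seed = 43)
  expect_identical(p1$assignments, p2$assignments)
  expect_false(identical(p1$assignments, p3$assignments))
})

test_that("a class smaller than k triggers the unstratified fallback", {
  y <- c(rep(1L, 3), rep(0L, 17))
  expect_warning(plan <- stratified_kfold(y, 5, seed = 1), "unstratified")
  expect_false(plan$stratified)
  expect_true(all(abs(diff(as.vector(table(plan$assignments)))) <= 1))
})

test_that("fold plans export as a two-column CSV", {
  plan <- stratified_kfold(rep(c(1L, 0L), 10), 4, seed = 2)
  path <- tempfile(fileext = ".csv")
  write_fold_plan(plan, path)
  df <- read.csv(path)
  expect_equal(names(df), c("case_id", "fold"))
  expect_equal(df$fold, plan$assignments)
})
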