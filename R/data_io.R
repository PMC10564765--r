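#' Construct a binary-labeled feature-selection dataset
#'
#' The basic container used throughout the package: an `n x m` numeric
#' feature matrix plus a binary label vector, where the positive class
#' conventionally marks "disease present". Missing values (`NA`) are allowed
#' at construction time; they must be removed with [clean_missing()] before
#' any model is fitted.
#'
#' @param x Numeric matrix or data frame of features (`n` cases by `m`
#'   features).
#' @param y Label vector of length `n` with exactly two distinct values, or a
#'   0/1 integer vector.
#' @param positive Value of `y` mapped to the positive class. When `y` is
#'   already 0/1 this defaults to `1`.
#' @param feature_names Character vector of `m` unique feature identifiers;
#'   defaults to the column names of `x`, or `f1..fm` when absent.
#'
#' @return An object of class `fs_dataset`: a list with elements `x` (numeric
#'   matrix), `y` (integer 0/1), `feature_names`, `positive_label`,
#'   `negative_label`, `n`, `m`.
#' @export
#' @examples
#' ds <- fs_dataset(matrix(rnorm(20), 10, 2), rep(c(1, 0), 5))
#' ds$n; ds$m
fs_dataset <- function(x, y, positive = NULL, feature_names = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) < 2L) stop("dataset must contain at least 2 cases")
  if (ncol(x) < 1L) stop("dataset must contain at least 1 feature")
  if (length(y) != nrow(x)) stop("length of 'y' must equal nrow(x)")
  if (anyNA(y)) stop("labels must not be missing")

  vals <- unique(y)
  if (length(vals) < 2L) stop("single-class dataset: labels contain one class")
  if (length(vals) > 2L) stop("labels contain more than two distinct values")

  if (is.null(positive)) {
    if (all(vals %in% c(0L, 1L)) || all(vals %in% c(0, 1))) {
      positive <- vals[vals == 1][1L]
    } else {
      stop("'positive' must name the positive class when labels are not 0/1")
    }
  }
  if (!positive %in% vals) stop("positive label not present in 'y'")
  negative <- vals[vals != positive][1L]

  fn <- feature_names %||% colnames(x) %||% paste0("f", seq_len(ncol(x)))
  if (length(fn) != ncol(x)) stop("feature_names length must equal ncol(x)")
  if (anyDuplicated(fn)) stop("feature names must be unique")
  colnames(x) <- fn

  structure(list(
    x = x,
    y = as.integer(y == positive),
    feature_names = as.character(fn),
    positive_label = positive,
    negative_label = negative,
    n = nrow(x),
    m = ncol(x)
  ), class = "fs_dataset")
}

#' @export
print.fs_dataset <- function(x, ...) {
  cat(sprintf(
    "<fs_dataset> %d cases (%d positive / %d negative), %d features\n",
    x$n, sum(x$y == 1L), sum(x$y == 0L), x$m))
  if (anyNA(x$x))
    cat(sprintf("  %d missing cells (call clean_missing() before modelling)\n",
                sum(is.na(x$x))))
  invisible(x)
}

#' Describe how to parse a delimited dataset file
#'
#' @param label_column Name (or 1-based index) of the label column.
#' @param positive_label Raw value in the label column mapped to the positive
#'   class; never inferred from lexical order.
#' @param delimiter Field separator character.
#' @param missing_markers Raw tokens treated as missing values.
#'
#' @return An object of class `fs_schema`.
#' @export
dataset_schema <- function(label_column, positive_label, delimiter = ",",
                           missing_markers = c("NA", "?", "")) {
  if (missing(label_column) || missing(positive_label))
    stop("'label_column' and 'positive_label' are required")
  structure(list(
    label_column = label_column,
    positive_label = positive_label,
    delimiter = delimiter,
    missing_markers = as.character(missing_markers)
  ), class = "fs_schema")
}

#' Read a dataset schema from a YAML or JSON config file
#'
#' The file must define `label_column` and `positive_label`; `delimiter` and
#' `missing_markers` are optional.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `fs_schema` object.
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) stop("schema file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  dataset_schema(
    label_column = cfg$label_column,
    positive_label = cfg$positive_label,
    delimiter = cfg$delimiter %||% ",",
    missing_markers = cfg$missing_markers %||% c("NA", "?", "")
  )
}

#' Load a delimited dataset file under a schema
#'
#' Reads a headered delimited text file, maps the label column to binary
#' classes, and converts every other column to numeric. Missing-value tokens
#' listed in the schema become `NA` and are retained; cleaning is a separate
#' step ([clean_missing()]).
#'
#' @param path Path to the data file.
#' @param schema An `fs_schema` from [dataset_schema()] or [read_schema()].
#' @return An `fs_dataset` (possibly containing `NA` cells).
#' @export
load_dataset <- function(path, schema) {
  if (!inherits(schema, "fs_schema")) stop("'schema' must be an fs_schema")
  if (!file.exists(path)) stop("data file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = schema$delimiter,
                          na.strings = schema$missing_markers,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  lc <- schema$label_column
  if (is.numeric(lc)) {
    if (lc < 1 || lc > ncol(df)) stop("label column index out of range")
    lab_idx <- as.integer(lc)
  } else {
    lab_idx <- match(lc, colnames(df))
    if (is.na(lab_idx)) stop("label column '", lc, "' absent from file")
  }
  y_raw <- df[[lab_idx]]
  if (anyNA(y_raw)) stop("missing values in the label column")
  vals <- unique(y_raw)
  if (length(vals) < 2L) stop("single-class dataset")
  if (!schema$positive_label %in% vals)
    stop("positive label '", schema$positive_label, "' not found in label column")

  xdf <- df[, -lab_idx, drop = FALSE]
  x <- vapply(xdf, function(col) suppressWarnings(as.numeric(col)),
              numeric(nrow(df)))
  dim(x) <- c(nrow(df), ncol(xdf))
  colnames(x) <- colnames(xdf)
  fs_dataset(x, y_raw, positive = schema$positive_label)
}

#' Remove missing values from a dataset
#'
#' Implements the two-stage cleaning rule used for heavily incomplete
#' clinical files: first drop the `drop_worst_vars` features with the most
#' missing cells (ties broken by lower column index), then drop every case
#' that still has a missing cell.
#'
#' @param ds An `fs_dataset`.
#' @param drop_worst_vars Number of worst-missing features to remove first.
#' @return A cleaned `fs_dataset` with no missing cells.
#' @export
clean_missing <- function(ds, drop_worst_vars = 0L) {
  stopifnot(inherits(ds, "fs_dataset"))
  if (drop_worst_vars < 0) stop("'drop_worst_vars' must be >= 0")
  x <- ds$x
  y <- ds$y
  if (drop_worst_vars > 0L) {
    if (drop_worst_vars >= ncol(x)) stop("cannot drop all features")
    miss <- colSums(is.na(x))
    drop <- order(-miss, seq_along(miss))[seq_len(drop_worst_vars)]
    x <- x[, -drop, drop = FALSE]
  }
  keep <- !apply(is.na(x), 1L, any)
  if (!any(keep)) stop("cleaning removed every case")
  x <- x[keep, , drop = FALSE]
  y <- y[keep]
  if (length(unique(y)) < 2L) stop("cleaning left a single-class dataset")
  out <- fs_dataset(x, y, positive = 1L)
  out$positive_label <- ds$positive_label
  out$negative_label <- ds$negative_label
  out
}

#' Standardize features on training statistics
#'
#' Per-feature standardization fitted on `train` only and applied unchanged
#' to each dataset in `others` (test folds), so no test information leaks
#' into the transform. The default is the z-score with the population
#' standard deviation (denominator `n`); `"minmax"` rescales to the training
#' min-max range. Constant training features map to all-zeros in every
#' dataset.
#'
#' @param train An `fs_dataset` the statistics are fitted on.
#' @param others A list of `fs_dataset`s (or a single one) sharing `train`'s
#'   feature names, transformed with the training statistics.
#' @param method `"zscore"` (default) or `"minmax"`.
#' @return A list with elements `train` and `others` (a list, possibly
#'   empty), all transformed.
#' @export
normalize_features <- function(train, others = list(),
                               method = c("zscore", "minmax")) {
  stopifnot(inherits(train, "fs_dataset"))
  method <- match.arg(method)
  if (inherits(others, "fs_dataset")) others <- list(others)
  for (o in others) {
    if (!identical(o$feature_names, train$feature_names))
      stop("datasets in 'others' must share the training feature names")
  }
  if (anyNA(train$x)) stop("normalize requires a dataset with no missing cells")

  if (method == "zscore") {
    center <- colMeans(train$x)
    scale_ <- sqrt(colMeans(sweep(train$x, 2L, center)^2))
  } else {
    center <- apply(train$x, 2L, min)
    scale_ <- apply(train$x, 2L, max) - center
  }
  const <- scale_ == 0
  scale_[const] <- 1

  apply_tf <- function(ds) {
    z <- sweep(sweep(ds$x, 2L, center), 2L, scale_, "/")
    z[, const] <- 0
    out <- ds
    out$x <- z
    out
  }
  list(train = apply_tf(train), others = lapply(others, apply_tf))
}

#' Stratified k-fold partition of a dataset
#'
#' Deterministic given `seed`. With stratification (the default) each class
#' is shuffled and dealt round-robin so per-class fold counts differ by at
#' most one; overall fold sizes also differ by at most one. If any class has
#' fewer than `k` members the plan falls back to an unstratified shuffle with
#' a warning.
#'
#' @param ds An `fs_dataset` (or a 0/1 label vector).
#' @param k Number of folds, `2 <= k <= n`.
#' @param seed Integer seed controlling the shuffle.
#' @param stratify Stratify folds by class (default `TRUE`).
#' @return An object of class `fold_plan`: list with `k`, `seed`,
#'   `assignments` (length-n integer vector of fold ids in `1..k`) and
#'   `stratified`.
#' @export
stratified_kfold <- function(ds, k, seed = 1L, stratify = TRUE) {
  y <- if (inherits(ds, "fs_dataset")) ds$y else as.integer(ds)
  n <- length(y)
  if (k < 2L || k > n) stop("'k' must satisfy 2 <= k <= n")
  if (stratify && min(table(y)) < k) {
    warning("a class has fewer than k members; falling back to unstratified folds")
    stratify <- FALSE
  }
  assignments <- integer(n)
  withr::with_seed(as.integer(seed), {
    if (stratify) {
      offset <- 0L
      for (cls in sort(unique(y))) {
        idx <- which(y == cls)
        idx <- idx[sample.int(length(idx))]
        assignments[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
        offset <- (offset + length(idx)) %% k
      }
    } else {
      idx <- sample.int(n)
      assignments[idx] <- ((seq_len(n) - 1L) %% k) + 1L
    }
  })
  structure(list(k = as.integer(k), seed = as.integer(seed),
                 assignments = assignments, stratified = stratify),
            class = "fold_plan")
}

#' Train/test indices for one fold of a plan
#'
#' @param plan A `fold_plan`.
#' @param fold Fold id in `1..k`; that fold is the test set, the rest train.
#' @return List with integer index vectors `train` and `test`.
#' @export
fold_split <- function(plan, fold) {
  stopifnot(inherits(plan, "fold_plan"))
  if (fold < 1L || fold > plan$k) stop("fold id out of range")
  test <- which(plan$assignments == fold)
  list(train = which(plan$assignments != fold), test = test)
}

#' Write a fold plan as a two-column CSV (case_id, fold)
#'
#' @param plan A `fold_plan`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fold_plan <- function(plan, path) {
  stopifnot(inherits(plan, "fold_plan"))
  utils::write.csv(
    data.frame(case_id = seq_along(plan$assignments), fold = plan$assignments),
    path, row.names = FALSE)
  invisible(path)
}

# Restrict a dataset to a row index set (internal).
subset_cases <- function(ds, idx) {
  out <- ds
  out$x <- ds$x[idx, , drop = FALSE]
  out$y <- ds$y[idx]
  out$n <- length(idx)
  out
}
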