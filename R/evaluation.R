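#' Tally a 2x2 confusion table
#'
#' @param y_true True labels.
#' @param y_pred Predicted labels (same coding as `y_true`).
#' @param positive Value marking the positive class (default `1`).
#' @return Object of class `confusion_counts`: named integer vector with
#'   elements `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(y_true, y_pred, positive = 1L) {
  if (length(y_true) != length(y_pred)) stop("label vectors differ in length")
  if (length(y_true) == 0L) stop("empty label vectors")
  tpos <- y_true == positive
  ppos <- y_pred == positive
  structure(c(tp = sum(tpos & ppos), tn = sum(!tpos & !ppos),
              fp = sum(!tpos & ppos), fn = sum(tpos & !ppos)),
            class = "confusion_counts")
}

check_counts <- function(counts) {
  if (!all(c("tp", "tn", "fp", "fn") %in% names(counts)))
    stop("counts must carry tp, tn, fp, fn")
  counts
}

#' Classification metrics from confusion counts
#'
#' The four reported metrics, computed exactly from the printed formulas:
#' * `metric_acc`: `(TP + TN) / (TP + FP + TN + FN)`
#' * `metric_auc`: `(1 + TP/(TP+FN) - FP/(TN+FP)) / 2` — a single-table
#'   balanced-accuracy form of the AUC, **not** a ROC-curve integral
#' * `metric_gmean`: `sqrt(TPR * TNR)`
#' * `metric_f1`: `2*TP / (2*TP + FP + FN)`
#'
#' When a denominator is zero (a fold with no positives or no negatives)
#' the metric is `NaN` with a warning; such folds are excluded from t-test
#' pairings rather than silently scored 0.
#'
#' @param counts A [confusion_counts()] (or any named vector with
#'   `tp`, `tn`, `fp`, `fn`).
#' @return Numeric score in `[0, 1]`, or `NaN` when undefined.
#' @name metrics
NULL

rates <- function(counts) {
  counts <- check_counts(counts)
  tp <- counts[["tp"]]; tn <- counts[["tn"]]
  fp <- counts[["fp"]]; fn <- counts[["fn"]]
  tpr <- if (tp + fn == 0) {
    warning("no positive cases: TPR undefined"); NaN
  } else tp / (tp + fn)
  tnr <- if (tn + fp == 0) {
    warning("no negative cases: TNR undefined"); NaN
  } else tn / (tn + fp)
  list(tp = tp, tn = tn, fp = fp, fn = fn, tpr = tpr, tnr = tnr)
}

#' @rdname metrics
#' @export
metric_acc <- function(counts) {
  counts <- check_counts(counts)
  total <- sum(counts[c("tp", "tn", "fp", "fn")])
  if (total == 0) stop("empty confusion table")
  (counts[["tp"]] + counts[["tn"]]) / total
}

#' @rdname metrics
#' @export
metric_auc <- function(counts) {
  r <- rates(counts)
  (1 + r$tpr - (1 - r$tnr)) / 2
}

#' @rdname metrics
#' @export
metric_gmean <- function(counts) {
  r <- rates(counts)
  sqrt(r$tpr * r$tnr)
}

#' @rdname metrics
#' @export
metric_f1 <- function(counts) {
  counts <- check_counts(counts)
  denom <- 2 * counts[["tp"]] + counts[["fp"]] + counts[["fn"]]
  if (denom == 0) {
    warning("no positive cases or predictions: F1 undefined")
    return(NaN)
  }
  2 * counts[["tp"]] / denom
}

all_metrics <- function(counts) {
  c(acc = metric_acc(counts), auc = metric_auc(counts),
    gmean = metric_gmean(counts), f1 = metric_f1(counts))
}

#' Paired two-tailed t-test between per-fold scores
#'
#' Classical paired t-test on the fold-aligned differences `a - b`
#' (delegating to [stats::t.test()]), returning a three-way verdict at the
#' given significance level: `"+"` when the difference is significant and
#' favors `a`, `"-"` when it favors `b`, `"="` otherwise. Pairs where either
#' score is `NA`/`NaN` (undefined metrics) are excluded. Zero-variance
#' differences are handled explicitly: all-zero differences give `t = 0`,
#' `p = 1`, verdict `"="`; constant non-zero differences give an infinite t
#' statistic, `p = 0`, a sign verdict, and `degenerate = TRUE`.
#'
#' @param a,b Equal-length numeric vectors of per-fold scores, aligned by
#'   fold.
#' @param level Two-sided significance level for the verdict.
#' @return Object of class `fs_ttest`: list with `t`, `p`, `df`,
#'   `mean_diff`, `n_pairs`, `verdict`, `degenerate`.
#' @export
paired_t_test <- function(a, b, level = 0.05) {
  if (length(a) != length(b)) stop("'a' and 'b' must have equal length")
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2L) stop("need at least 2 complete pairs")
  d <- a - b
  md <- mean(d)
  # same degeneracy rule t.test applies, caught before it can error
  stderr <- sd(d) / sqrt(length(d))
  if (stderr == 0 || stderr < 10 * .Machine$double.eps * abs(md)) {
    if (md == 0) {
      res <- list(t = 0, p = 1, df = length(d) - 1L, mean_diff = 0,
                  n_pairs = length(d), verdict = "=", degenerate = FALSE)
    } else {
      res <- list(t = sign(md) * Inf, p = 0, df = length(d) - 1L,
                  mean_diff = md, n_pairs = length(d),
                  verdict = if (md > 0) "+" else "-", degenerate = TRUE)
    }
    return(structure(res, class = "fs_ttest"))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  verdict <- if (tt$p.value < level) {
    if (md > 0) "+" else "-"
  } else "="
  structure(list(t = unname(tt$statistic), p = tt$p.value,
                 df = unname(tt$parameter), mean_diff = md,
                 n_pairs = length(d), verdict = verdict, degenerate = FALSE),
            class = "fs_ttest")
}

#' @export
print.fs_ttest <- function(x, ...) {
  cat(sprintf("<fs_ttest> t = %.4f, df = %d, p = %.4g, verdict '%s'%s\n",
              x$t, x$df, x$p, x$verdict,
              if (x$degenerate) " (degenerate: zero-variance differences)" else ""))
  invisible(x)
}

#' Cross-validated feature-selection experiment
#'
#' The full experimental protocol: split the dataset into `k` stratified
#' folds; for each fold, standardize the training part and carry the
#' transform to the test part, run [multistart_tabu()] on the training data,
#' refit the classifier on the training data with the selected subset, and
#' score the held-out fold with the four confusion-matrix metrics. Per-fold
#' search seeds are derived deterministically from `seed`, so the whole
#' experiment is reproducible.
#'
#' @param ds A cleaned `fs_dataset` (raw scale; normalization happens
#'   per fold).
#' @param cfg An [objective_config()].
#' @param params A [search_params()] (its `seed` is re-derived per fold).
#' @param k Number of folds.
#' @param seed Master seed for the fold plan and the per-fold searches.
#' @param normalize_method Passed to [normalize_features()].
#' @return Object of class `fs_cv`: list with `records` (one row per fold:
#'   selected subset, train `f`/`rat`, test confusion counts and metrics,
#'   wall time), `summary` (mean and sd per metric, on the raw scale and
#'   formatted as percentages to 2 decimals), `plan`, and `selected` (list
#'   of per-fold selected feature names).
#' @export
run_cv_experiment <- function(ds, cfg = objective_config(),
                              params = search_params(), k = 10L, seed = 1L,
                              normalize_method = "zscore") {
  stopifnot(inherits(ds, "fs_dataset"))
  if (anyNA(ds$x)) stop("dataset contains missing cells; clean it first")
  plan <- stratified_kfold(ds, k, seed = seed)
  records <- vector("list", k)
  selected <- vector("list", k)

  for (fold in seq_len(k)) {
    t0 <- proc.time()[["elapsed"]]
    idx <- fold_split(plan, fold)
    train <- subset_cases(ds, idx$train)
    test <- subset_cases(ds, idx$test)
    norm <- normalize_features(train, list(test), method = normalize_method)
    train <- norm$train
    test <- norm$others[[1L]]

    fold_params <- params
    fold_params$seed <- as.integer(seed) + 7919L * fold
    res <- multistart_tabu(train, cfg, fold_params)

    model <- do.call(fit_classifier,
                     c(list(train, res$best_subset, kind = cfg$classifier),
                       cfg$fit_args))
    pred <- predict(model, test)
    counts <- confusion_counts(test$y, pred, positive = 1L)
    mets <- suppressWarnings(all_metrics(counts))
    records[[fold]] <- data.frame(
      fold = fold,
      n_selected = length(res$best_subset),
      train_f = res$best_f,
      train_rat = res$best_rat,
      tp = counts[["tp"]], tn = counts[["tn"]],
      fp = counts[["fp"]], fn = counts[["fn"]],
      acc = mets[["acc"]], auc = mets[["auc"]],
      gmean = mets[["gmean"]], f1 = mets[["f1"]],
      seconds = proc.time()[["elapsed"]] - t0)
    selected[[fold]] <- res$best_feature_names
  }

  records <- do.call(rbind, records)
  metric_cols <- c("train_f", "acc", "auc", "gmean", "f1")
  means <- vapply(records[metric_cols], function(v) mean(v, na.rm = TRUE),
                  numeric(1L))
  sds <- vapply(records[metric_cols], function(v) sd(v, na.rm = TRUE),
                numeric(1L))
  summary <- data.frame(
    metric = metric_cols,
    mean = means,
    sd = sds,
    formatted = sprintf("%.2f ± %.2f", 100 * means, 100 * sds),
    row.names = NULL)

  structure(list(records = records, summary = summary, plan = plan,
                 selected = selected, k = as.integer(k),
                 seed = as.integer(seed), classifier = cfg$classifier),
            class = "fs_cv")
}

#' @export
print.fs_cv <- function(x, ...) {
  cat(sprintf("<fs_cv> %d-fold cross-validation, classifier '%s'\n",
              x$k, x$classifier))
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-9s %s\n", x$summary$metric[i], x$summary$formatted[i]))
  invisible(x)
}
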