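#' Classifier registry
#'
#' The wrapper evaluates feature subsets with a classifier behind a single
#' fit/predict contract. Three kinds are built in:
#'
#' * `"da"` — linear discriminant analysis with pooled covariance and
#'   empirical class priors (closed form, compiled); singular covariance
#'   falls back to a diagonal ridge (`1e-6`) with a warning.
#' * `"lr"` — logistic regression via [stats::glm()] (IRLS), posterior 0.5
#'   threshold; non-convergence returns the last iterate with a warning.
#' * `"svm"` — linear support vector machine via [e1071::svm()], cost 1,
#'   sign of the decision value.
#'
#' Additional classifiers can be plugged in with [register_classifier()].
#'
#' @name classifiers
NULL

.classifier_registry <- new.env(parent = emptyenv())

#' Register a classifier kind
#'
#' @param name Short lowercase identifier (e.g. `"da"`).
#' @param fit_fun Function `(x, y, ...)` taking a numeric matrix restricted
#'   to the candidate subset and an integer 0/1 label vector, returning an
#'   object with a `predict_fun(object, x)` returning integer 0/1.
#' @param predict_fun Function `(object, x)` producing 0/1 predictions.
#' @return `name`, invisibly.
#' @export
register_classifier <- function(name, fit_fun, predict_fun) {
  stopifnot(is.character(name), length(name) == 1L,
            is.function(fit_fun), is.function(predict_fun))
  assign(name, list(fit = fit_fun, predict = predict_fun),
         envir = .classifier_registry)
  invisible(name)
}

#' List registered classifier kinds
#' @return Character vector of kind names.
#' @export
classifier_kinds <- function() sort(ls(.classifier_registry))

get_classifier <- function(kind) {
  if (!exists(kind, envir = .classifier_registry, inherits = FALSE))
    stop("unknown classifier kind '", kind, "'; registered: ",
         paste(classifier_kinds(), collapse = ", "))
  get(kind, envir = .classifier_registry, inherits = FALSE)
}

# ---- built-in kinds --------------------------------------------------------

fit_da_core <- function(x, y, ridge = 1e-6) {
  f <- .lda_fit(x, as.integer(y), seq_len(ncol(x)), ridge)
  if (isTRUE(f$used_ridge))
    warning("singular within-class covariance; using diagonal ridge ", ridge)
  f
}

predict_da_core <- function(object, x) {
  as.integer(drop(x %*% object$w) + object$b >= 0)
}

fit_lr_core <- function(x, y, maxit = 1000L, tol = 1e-4) {
  df <- as.data.frame(x)
  names(df) <- paste0("V", seq_len(ncol(x)))
  df$.y <- y
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = df, family = stats::binomial(),
               control = list(maxit = maxit, epsilon = tol)))
  if (!fit$converged)
    warning("logistic regression did not converge; using last iterate")
  list(coef = stats::coef(fit))
}

predict_lr_core <- function(object, x) {
  beta <- object$coef
  beta[is.na(beta)] <- 0
  eta <- drop(cbind(1, x) %*% beta)
  as.integer(eta >= 0)  # posterior >= 0.5
}

fit_svm_core <- function(x, y, cost = 1, tolerance = 1e-4) {
  fit <- e1071::svm(x, factor(y, levels = c(0L, 1L)), kernel = "linear",
                    cost = cost, tolerance = tolerance, scale = FALSE)
  list(fit = fit)
}

predict_svm_core <- function(object, x) {
  as.integer(as.character(predict(object$fit, x)))
}

register_builtin_classifiers <- function() {
  register_classifier("da", fit_da_core, predict_da_core)
  register_classifier("lr", fit_lr_core, predict_lr_core)
  register_classifier("svm", fit_svm_core, predict_svm_core)
}

.onLoad <- function(libname, pkgname) {
  register_builtin_classifiers()
}

# ---- user-facing contract --------------------------------------------------

#' Fit a classifier on a feature subset
#'
#' @param ds An `fs_dataset` with no missing cells and both classes present.
#' @param subset Integer vector of feature indices (1-based, non-empty) or a
#'   character vector of feature names.
#' @param kind Classifier kind; one of [classifier_kinds()].
#' @param ... Passed to the kind's fit function (e.g. `cost`, `maxit`).
#' @return An object of class `fs_model` recording the kind, the fitted
#'   parameters and the subset it was trained on.
#' @export
fit_classifier <- function(ds, subset, kind = "da", ...) {
  stopifnot(inherits(ds, "fs_dataset"))
  subset <- resolve_subset(ds, subset)
  if (length(subset) == 0L) stop("empty feature subset")
  if (length(unique(ds$y)) < 2L) stop("training data must contain both classes")
  cls <- get_classifier(kind)
  fitted <- cls$fit(ds$x[, subset, drop = FALSE], ds$y, ...)
  structure(list(kind = kind, fitted = fitted, subset = subset,
                 feature_names = ds$feature_names[subset]),
            class = "fs_model")
}

#' @export
print.fs_model <- function(x, ...) {
  cat(sprintf("<fs_model> %s on %d feature(s): %s\n", x$kind,
              length(x$subset), paste(x$feature_names, collapse = ", ")))
  invisible(x)
}

#' Predict binary labels with a fitted model
#'
#' The model extracts its own features from `newdata`, matched by name; a
#' dataset that lacks any of the model's features is a contract violation.
#'
#' @param object An `fs_model`.
#' @param newdata An `fs_dataset` or numeric matrix with named columns
#'   containing the model's features.
#' @param ... Unused.
#' @return Integer 0/1 vector, one prediction per case.
#' @export
predict.fs_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "fs_dataset")) newdata$x else as.matrix(newdata)
  pos <- match(object$feature_names, colnames(x))
  if (anyNA(pos))
    stop("newdata lacks model feature(s): ",
         paste(object$feature_names[is.na(pos)], collapse = ", "))
  cls <- get_classifier(object$kind)
  cls$predict(object$fitted, x[, pos, drop = FALSE])
}

resolve_subset <- function(ds, subset) {
  if (is.character(subset)) {
    idx <- match(subset, ds$feature_names)
    if (anyNA(idx)) stop("unknown feature name(s): ",
                         paste(subset[is.na(idx)], collapse = ", "))
    subset <- idx
  }
  subset <- as.integer(subset)
  if (anyDuplicated(subset)) stop("duplicate feature indices in subset")
  if (length(subset) && (min(subset) < 1L || max(subset) > ds$m))
    stop("feature index out of range 1..m")
  sort(subset)
}
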