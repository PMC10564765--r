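#' Configuration of the composite selection objective
#'
#' The search maximizes `f(S) = beta * Rat(S) + (1 - beta) * (1 - |S|/m)`,
#' where `Rat(S)` is the resubstitution rate: the fraction of training cases
#' correctly classified by a model fitted on the training data restricted to
#' `S`. `beta` trades classifying capacity against parsimony; values at or
#' near 0.99 are customary and 0.99 is the default.
#'
#' @param beta Weight in `[0, 1]` on the resubstitution rate.
#' @param classifier Classifier kind used to compute `Rat` (see
#'   [classifier_kinds()]).
#' @param ridge Diagonal regularization used by the DA fallback for singular
#'   covariance.
#' @param ... Extra arguments stored and passed to the classifier fit.
#' @return An object of class `objective_config`.
#' @export
objective_config <- function(beta = 0.99, classifier = "da", ridge = 1e-6, ...) {
  if (beta < 0 || beta > 1) stop("'beta' must lie in [0, 1]")
  structure(list(beta = beta, classifier = classifier, ridge = ridge,
                 fit_args = list(...)),
            class = "objective_config")
}

#' Composite objective value
#'
#' `beta * rat_value + (1 - beta) * (1 - subset_size / m)`, with the
#' convention that the empty subset scores exactly 0 (the formula is
#' overridden; `rat_value` is ignored when `subset_size == 0`).
#'
#' @param rat_value Resubstitution rate in `[0, 1]` (vectorized).
#' @param subset_size Number of selected features, `0..m`.
#' @param m Size of the feature universe.
#' @param beta Weight in `[0, 1]`.
#' @return Numeric score(s) in `[0, 1]`.
#' @export
#' @examples
#' objective_f(0.8, 5, 22, 0.99)  # 0.99*0.8 + 0.01*(1 - 5/22)
#' objective_f(0.8, 0, 22, 0.99)  # empty-subset convention: 0
objective_f <- function(rat_value, subset_size, m, beta) {
  if (any(subset_size < 0 | subset_size > m)) stop("subset_size must lie in 0..m")
  out <- beta * rat_value + (1 - beta) * (1 - subset_size / m)
  out[subset_size == 0] <- 0
  out
}

#' Resubstitution rate of a subset
#'
#' Fits the configured classifier on `ds` restricted to `subset` and returns
#' the fraction of the same training cases it classifies correctly. This is
#' deliberately an optimistic training-set rate: it is the quantity the
#' search objective is defined on, not a generalization estimate.
#'
#' @param ds An `fs_dataset` (normalized, no missing cells).
#' @param subset Non-empty integer index vector (or feature names).
#' @param cfg An [objective_config()].
#' @return Fraction in `[0, 1]`.
#' @export
rat_score <- function(ds, subset, cfg = objective_config()) {
  subset <- resolve_subset(ds, subset)
  if (length(subset) == 0L) stop("empty feature subset")
  if (cfg$classifier == "da") {
    stats <- .lda_make_stats(ds$x, ds$y)
    .lda_rat_batch(ds$x, ds$y, stats, list(subset), cfg$ridge)[[1L]]
  } else {
    model <- do.call(fit_classifier,
                     c(list(ds, subset, kind = cfg$classifier), cfg$fit_args))
    mean(predict(model, ds) == ds$y)
  }
}

#' Create an evaluation cache
#'
#' Tabu search revisits subsets heavily and classifier fits dominate
#' runtime, so evaluated `(rat, f)` pairs are memoized under a canonical
#' (order-independent) subset key. The cache is exact: a hit returns the
#' stored value unchanged.
#'
#' @param max_entries Optional cap on stored subsets; once reached, new
#'   results are computed but not stored.
#' @return An object of class `evaluation_cache` (an environment with
#'   `hits`/`misses` counters).
#' @export
evaluation_cache <- function(max_entries = Inf) {
  cache <- new.env(parent = emptyenv())
  cache$store <- new.env(parent = emptyenv())
  cache$hits <- 0L
  cache$misses <- 0L
  cache$size <- 0L
  cache$max_entries <- max_entries
  class(cache) <- "evaluation_cache"
  cache
}

#' @export
print.evaluation_cache <- function(x, ...) {
  cat(sprintf("<evaluation_cache> %d entries, %d hits / %d misses\n",
              x$size, x$hits, x$misses))
  invisible(x)
}

subset_key <- function(subset) paste(sort(subset), collapse = ",")

# Sufficient statistics for the fast DA evaluator (pooled scatter, class
# means); memoized on the cache when one is supplied, since a cache lives for
# exactly one dataset/search run.
lda_stats <- function(ds, cache = NULL) {
  if (!is.null(cache) && !is.null(cache$lda_stats)) return(cache$lda_stats)
  stats <- .lda_make_stats(ds$x, ds$y)
  if (!is.null(cache)) cache$lda_stats <- stats
  stats
}

#' Evaluate a subset under the objective, through the cache
#'
#' Returns the same `(rat, f)` whether served from cache or computed. The
#' empty subset returns `f = 0` by convention without fitting any model
#' (`rat` is `NA`).
#'
#' @param ds An `fs_dataset`.
#' @param subset Integer index vector (possibly empty).
#' @param cfg An [objective_config()].
#' @param cache An [evaluation_cache()] or `NULL` to compute uncached.
#' @return Named numeric vector `c(rat = ..., f = ...)`.
#' @export
evaluate_subset <- function(ds, subset, cfg = objective_config(), cache = NULL) {
  if (length(subset) == 0L) return(c(rat = NA_real_, f = 0))
  res <- evaluate_subsets(ds, list(subset), cfg, cache)
  c(rat = res$rat[[1L]], f = res$f[[1L]])
}

#' Evaluate a batch of subsets, through the cache
#'
#' The batched entry point used by the search: uncached subsets are computed
#' in one pass (a single compiled call for DA) and stored.
#'
#' @inheritParams evaluate_subset
#' @param subsets List of integer index vectors (all non-empty).
#' @return List with numeric vectors `rat` and `f`, aligned with `subsets`.
#' @export
evaluate_subsets <- function(ds, subsets, cfg = objective_config(), cache = NULL) {
  stopifnot(inherits(ds, "fs_dataset"))
  ns <- length(subsets)
  rat <- numeric(ns)
  if (ns == 0L) return(list(rat = rat, f = rat))
  keys <- vapply(subsets, subset_key, character(1L))
  sizes <- lengths(subsets)
  if (any(sizes == 0L)) stop("evaluate_subsets requires non-empty subsets")

  if (is.null(cache)) {
    todo <- seq_len(ns)
  } else {
    cached <- vapply(keys, function(k)
      exists(k, envir = cache$store, inherits = FALSE), logical(1L))
    todo <- which(!cached)
    hit <- which(cached)
    cache$hits <- cache$hits + length(hit)
    for (i in hit) rat[i] <- get(keys[i], envir = cache$store, inherits = FALSE)
  }

  if (length(todo)) {
    # duplicate keys within one batch are computed once
    uk <- !duplicated(keys[todo])
    comp_idx <- todo[uk]
    vals <- if (cfg$classifier == "da") {
      .lda_rat_batch(ds$x, ds$y, lda_stats(ds, cache), subsets[comp_idx],
                     cfg$ridge)
    } else {
      vapply(subsets[comp_idx], function(s) rat_score(ds, s, cfg), numeric(1L))
    }
    lookup <- stats::setNames(vals, keys[comp_idx])
    rat[todo] <- lookup[keys[todo]]
    if (!is.null(cache)) {
      # one classifier fit per unique uncached subset
      cache$misses <- cache$misses + length(comp_idx)
      for (i in seq_along(comp_idx)) {
        if (cache$size < cache$max_entries) {
          assign(keys[comp_idx[i]], vals[[i]], envir = cache$store)
          cache$size <- cache$size + 1L
        }
      }
    }
  }
  list(rat = rat, f = objective_f(rat, sizes, ds$m, cfg$beta))
}
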