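#' Specification of a synthetic benchmark dataset
#'
#' Describes a two-class Gaussian dataset in the shape of typical clinical
#' diagnosis tables: `r` informative features whose class-conditional means
#' are separated by `delta` standard deviations, and `m - r` pure-noise
#' features independent of the class. Class-conditional Gaussians are used
#' deliberately: pooled-covariance discriminant analysis is Bayes-optimal
#' there, so "the informative subset is the good subset" holds by
#' construction rather than by assumption.
#'
#' @param n Number of cases.
#' @param m Number of features.
#' @param r Number of informative features (`0 < r <= m`).
#' @param delta Class mean separation of informative features, in units of
#'   the per-feature standard deviation.
#' @param pos_fraction Fraction of positive cases, in `(0, 1)`.
#' @param noise_sd Per-feature standard deviation.
#' @param seed Integer seed; generation is deterministic per seed.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n = 300L, m = 10L, r = 3L, delta = 2,
                           pos_fraction = 0.5, noise_sd = 1, seed = 1L) {
  if (r <= 0 || r > m) stop("'r' must satisfy 0 < r <= m")
  if (pos_fraction <= 0 || pos_fraction >= 1)
    stop("'pos_fraction' must lie strictly between 0 and 1")
  if (delta < 0) stop("'delta' must be >= 0")
  if (noise_sd <= 0) stop("'noise_sd' must be > 0")
  structure(list(n = as.integer(n), m = as.integer(m), r = as.integer(r),
                 delta = delta, pos_fraction = pos_fraction,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic dataset with known informative features
#'
#' Draws labels with a fixed positive count `round(n * pos_fraction)`, then
#' features: the `r` informative features (indices chosen at random) are
#' `N(0, noise_sd)` for negatives and `N(delta * noise_sd, noise_sd)` for
#' positives; the remaining features are `N(0, noise_sd)` independent of the
#' class. Row order is shuffled. Deterministic per `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `dataset` (an `fs_dataset`) and `informative` (sorted
#'   integer indices of the truly informative features).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    n_pos <- round(spec$n * spec$pos_fraction)
    if (n_pos < 1 || n_pos > spec$n - 1)
      stop("class balance leaves a single-class dataset")
    y <- sample(c(rep(1L, n_pos), rep(0L, spec$n - n_pos)))
    informative <- sort(sample.int(spec$m, spec$r))
    x <- matrix(rnorm(spec$n * spec$m, sd = spec$noise_sd), spec$n, spec$m)
    shift <- spec$delta * spec$noise_sd
    x[y == 1L, informative] <- x[y == 1L, informative] + shift
    colnames(x) <- paste0("f", seq_len(spec$m))
    list(dataset = fs_dataset(x, y, positive = 1L), informative = informative)
  })
}

#' Write a synthetic dataset to CSV with a truth sidecar
#'
#' Emits `path` as a headered CSV (features plus a `class` column coded
#' `pos`/`neg`) and `<path>.truth.json` recording the informative feature
#' names and the generating spec.
#'
#' @param sim Result of [generate_synthetic()].
#' @param spec The [synthetic_spec()] that produced it.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_synthetic <- function(sim, spec, path) {
  ds <- sim$dataset
  df <- as.data.frame(ds$x)
  df$class <- ifelse(ds$y == 1L, "pos", "neg")
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(informative = ds$feature_names[sim$informative],
         spec = unclass(spec)),
    paste0(path, ".truth.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Exhaustively solve the subset-selection problem
#'
#' Enumerates every non-empty subset of the feature universe (plus the
#' empty-set convention entry, `f = 0`), evaluates the objective on each,
#' and returns the maximizer. Ties are broken toward the smallest subset,
#' then lexicographically — mirroring the objective's parsimony pressure and
#' making the oracle deterministic. Guarded at `m <= 15` (32,767 subsets),
#' the scale at which exhaustive enumeration stays a desk-time computation.
#'
#' @param ds An `fs_dataset`.
#' @param cfg An [objective_config()].
#' @param keep_landscape Return the full per-subset table (`m <= 12` only).
#' @return Object of class `fs_oracle`: list with `best_subset`, `best_f`,
#'   `best_rat`, `n_enumerated` (`2^m`, counting the empty-set entry), and
#'   optionally `landscape` (data frame: subset key, size, rat, f).
#' @export
exhaustive_best_subset <- function(ds, cfg = objective_config(),
                                   keep_landscape = FALSE) {
  stopifnot(inherits(ds, "fs_dataset"))
  m <- ds$m
  if (m > 15L)
    stop("exhaustive enumeration is guarded at m <= 15 (2^m subsets); ",
         "use multistart_tabu() for larger universes")
  if (keep_landscape && m > 12L) stop("'keep_landscape' requires m <= 12")

  n_sub <- bitwShiftL(1L, m) - 1L
  bits <- bitwShiftL(1L, seq_len(m) - 1L)
  subsets <- lapply(seq_len(n_sub), function(mask) which(bitwAnd(mask, bits) > 0L))
  res <- evaluate_subsets(ds, subsets, cfg, cache = NULL)

  best_f <- max(res$f)
  if (best_f <= 0) {
    best <- integer(0)
    best_f <- 0
    best_rat <- NA_real_
  } else {
    cand <- which(res$f == best_f)
    sz <- lengths(subsets[cand])
    cand <- cand[sz == min(sz)]
    if (length(cand) > 1L) {
      keymat <- t(vapply(subsets[cand], identity, integer(min(sz))))
      cand <- cand[do.call(order, as.data.frame(keymat))[1L]]
    }
    best <- subsets[[cand]]
    best_rat <- res$rat[[cand]]
  }

  out <- list(best_subset = best,
              best_feature_names = ds$feature_names[best],
              best_f = best_f, best_rat = best_rat,
              n_enumerated = n_sub + 1L)
  if (keep_landscape)
    out$landscape <- data.frame(
      subset = vapply(subsets, subset_key, character(1L)),
      size = lengths(subsets), rat = res$rat, f = res$f)
  structure(out, class = "fs_oracle")
}

#' @export
print.fs_oracle <- function(x, ...) {
  cat(sprintf("<fs_oracle> best f = %.4f over %d enumerated subsets\n",
              x$best_f, x$n_enumerated))
  cat("  best subset:", if (length(x$best_subset))
    paste(x$best_feature_names, collapse = ", ") else "(empty)", "\n")
  invisible(x)
}
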