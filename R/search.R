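#' Search parameters for the multistart tabu method
#'
#' Tuned defaults: `alpha = 0.99` (near-greedy construction),
#' `tenure = ceiling(m/2)`, `max_iter_ts = 10 * m`, `max_iter_ms = 10`,
#' where `m` is the number of features of the dataset the search runs on.
#' `tenure` and `max_iter_ts` are resolved from `m` at run time when left
#' `NULL`.
#'
#' @param alpha Greediness of the restricted candidate list, in `[0, 1]`:
#'   1 is fully greedy (deterministic up to ties), 0 samples uniformly from
#'   all improving candidates.
#' @param tenure Tabu tenure in iterations (`NULL` = `ceiling(m/2)`).
#' @param max_iter_ts Consecutive non-improving tabu iterations before a
#'   tabu run stops (`NULL` = `10 * m`).
#' @param max_iter_ms Consecutive non-improving starts before the multistart
#'   loop stops.
#' @param seed Integer seed; fixes the whole search trajectory.
#' @return An object of class `search_params`.
#' @export
search_params <- function(alpha = 0.99, tenure = NULL, max_iter_ts = NULL,
                          max_iter_ms = 10L, seed = 1L) {
  if (alpha < 0 || alpha > 1) stop("'alpha' must lie in [0, 1]")
  if (!is.null(tenure) && tenure < 0) stop("'tenure' must be >= 0")
  if (!is.null(max_iter_ts) && max_iter_ts < 1) stop("'max_iter_ts' must be >= 1")
  if (max_iter_ms < 1) stop("'max_iter_ms' must be >= 1")
  structure(list(alpha = alpha, tenure = tenure, max_iter_ts = max_iter_ts,
                 max_iter_ms = as.integer(max_iter_ms),
                 seed = as.integer(seed)),
            class = "search_params")
}

resolve_params <- function(params, m) {
  params$tenure <- as.integer(params$tenure %||% ceiling(m / 2))
  params$max_iter_ts <- as.integer(params$max_iter_ts %||% (10L * m))
  params
}

# Uniform draw from a vector. One unif_rand() consumption per call, the same
# scheme as the compiled tabu path, so R and compiled trajectories share the
# RNG stream exactly (and there is no sample(length-1) pitfall).
draw_one <- function(x) {
  k <- length(x)
  pick <- floor(stats::runif(1L) * k) + 1L
  x[[min(pick, k)]]
}

#' Objective gains of single-feature additions
#'
#' For every candidate feature `j` outside `subset`, the objective value
#' `g(j) = f(subset + j)` the subset would reach if `j` were added.
#'
#' @param ds An `fs_dataset`.
#' @param subset Current subset (integer indices, `|S| < m`).
#' @param cfg An [objective_config()].
#' @param cache Optional [evaluation_cache()].
#' @return Numeric vector of gains named by candidate feature index.
#' @export
greedy_gains <- function(ds, subset, cfg = objective_config(), cache = NULL) {
  cand <- setdiff(seq_len(ds$m), subset)
  if (length(cand) == 0L) stop("subset already contains every feature")
  subsets <- lapply(cand, function(j) c(subset, j))
  res <- evaluate_subsets(ds, subsets, cfg, cache)
  stats::setNames(res$f, cand)
}

#' Restricted-candidate-list selection
#'
#' Among candidates that would not worsen the current objective
#' (`g(j) >= current_f`, the improving list L'), keeps those within the top
#' `alpha` fraction of the gain range — `g(j) >= gmin + alpha * (gmax -
#' gmin)` with `gmin`/`gmax` taken over L' — and draws one uniformly at
#' random. At `alpha = 1` this is the greedy argmax; at `alpha = 0` it is a
#' uniform draw from all improving candidates.
#'
#' @param gains Named numeric vector as returned by [greedy_gains()].
#' @param current_f Objective value of the current subset.
#' @param alpha Greediness in `[0, 1]`.
#' @return The chosen feature index (integer), or `NA_integer_` when no
#'   candidate improves (`L'` empty) — the construction stops.
#' @export
rcl_select <- function(gains, current_f, alpha) {
  if (length(gains) == 0L) stop("'gains' must be non-empty")
  improving <- gains >= current_f
  if (!any(improving)) return(NA_integer_)
  g <- gains[improving]
  gmax <- max(g)
  gmin <- min(g)
  keep <- g >= gmin + alpha * (gmax - gmin)
  as.integer(draw_one(names(g)[keep]))
}

#' Greedy randomized construction of a starting subset
#'
#' Starts from the empty subset (objective 0, so every feature is initially
#' a candidate) and repeatedly adds an [rcl_select()] choice until no
#' candidate improves the objective or the subset is the full universe.
#' Every accepted feature satisfies `g(j) >= f(S)` at the moment it is
#' added, so construction terminates in at most `m` steps.
#'
#' @inheritParams greedy_gains
#' @param params A [search_params()] (only `alpha` is used).
#' @param audit Record per-step `(f_before, gain)` pairs for contract
#'   auditing.
#' @return List with `subset` (sorted integer vector), `f`, `rat`, and (if
#'   requested) `audit`, a data frame with one row per accepted feature.
#' @export
constructive <- function(ds, cfg = objective_config(), params = search_params(),
                         cache = NULL, audit = FALSE) {
  S <- integer(0)
  f_cur <- 0
  rat_cur <- NA_real_
  steps <- if (audit) vector("list", ds$m) else NULL
  k <- 0L
  while (length(S) < ds$m) {
    gains <- greedy_gains(ds, S, cfg, cache)
    j <- rcl_select(gains, f_cur, params$alpha)
    if (is.na(j)) break
    k <- k + 1L
    if (audit)
      steps[[k]] <- data.frame(step = k, feature = j, f_before = f_cur,
                               gain = unname(gains[as.character(j)]))
    S <- sort(c(S, j))
    ev <- evaluate_subset(ds, S, cfg, cache)
    f_cur <- ev[["f"]]
    rat_cur <- ev[["rat"]]
  }
  out <- list(subset = S, f = f_cur, rat = rat_cur)
  if (audit) out$audit <- do.call(rbind, steps[seq_len(k)])
  out
}

#' Tabu memory for add/remove moves
#'
#' Per-feature iteration stamps: `vector_in[j]` is the iteration at which
#' feature `j` last entered the current subset, `vector_out[j]` the
#' iteration at which it last left. Stamps are initialized to
#' `-(tenure + 1)` so that no move is tabu at iteration 1.
#'
#' @param m Feature universe size.
#' @param tenure Tabu tenure in iterations.
#' @return An object of class `tabu_memory`: list with `vector_in`,
#'   `vector_out`, `iter`.
#' @export
tabu_memory <- function(m, tenure) {
  init <- rep(-(as.integer(tenure) + 1L), m)
  structure(list(vector_in = init, vector_out = init, iter = 0L),
            class = "tabu_memory")
}

#' Tabu status of adding a feature
#'
#' The entry of feature `j` (currently outside the subset) is tabu while
#' `iter <= vector_out[j] + tenure`: a recently removed feature may not
#' re-enter for `tenure` iterations.
#'
#' @param mem A [tabu_memory()].
#' @param j Feature index.
#' @param tenure Tabu tenure.
#' @return Logical flag.
#' @export
is_entry_tabu <- function(mem, j, tenure) {
  mem$iter <= mem$vector_out[j] + tenure
}

#' Tabu status of removing a feature
#'
#' The exit of feature `j` (currently inside the subset) is tabu while
#' `iter <= vector_in[j] + tenure`. A swap is tabu when its entry or its
#' exit is tabu.
#'
#' @inheritParams is_entry_tabu
#' @return Logical flag.
#' @export
is_exit_tabu <- function(mem, j, tenure) {
  mem$iter <= mem$vector_in[j] + tenure
}

# Enumerate the full add/remove/swap neighborhood of S as a move table.
enumerate_moves <- function(S, m) {
  outside <- setdiff(seq_len(m), S)
  moves <- list()
  if (length(outside))
    moves$add <- data.frame(type = "add", j_in = outside, j_out = NA_integer_)
  if (length(S))
    moves$remove <- data.frame(type = "remove", j_in = NA_integer_, j_out = S)
  if (length(S) && length(outside)) {
    grid <- expand.grid(j_out = S, j_in = outside, KEEP.OUT.ATTRS = FALSE)
    moves$swap <- data.frame(type = "swap", j_in = grid$j_in, j_out = grid$j_out)
  }
  do.call(rbind, moves)
}

apply_move <- function(S, type, j_in, j_out) {
  if (type == "add") sort(c(S, j_in))
  else if (type == "remove") S[S != j_out]
  else sort(c(S[S != j_out], j_in))
}

#' Tabu search over add/remove/swap moves
#'
#' Best-improvement tabu search: each iteration enumerates the full
#' neighborhood `N(S)` (all single additions, removals, and swaps), discards
#' tabu moves unless they beat the best objective found in this run
#' (aspiration), and executes the considered neighbor with the highest
#' objective, ties broken uniformly at random. Moves to worse neighbors are
#' accepted; cycling is suppressed by the tenure-based memory. The run stops
#' after `max_iter_ts` consecutive iterations without improving the run
#' best `f*`.
#'
#' @inheritParams constructive
#' @param start Starting subset (integer indices; typically from
#'   [constructive()]).
#' @param audit Record a per-iteration audit of every candidate move
#'   (objective, tabu status, stamps, chosen flag) for mechanics checks;
#'   intended for small instances.
#' @return List with `subset` (`S*`), `f`, `rat`, `iterations`, `trace`
#'   (data frame: iteration, f of the executed neighbor, running best), and
#'   optionally `audit` (list of per-iteration data frames).
#' @export
tabu_search <- function(ds, cfg = objective_config(), start = integer(0),
                        params = search_params(), cache = NULL, audit = FALSE) {
  stopifnot(inherits(ds, "fs_dataset"))
  params <- resolve_params(params, ds$m)
  tenure <- params$tenure
  S <- resolve_subset(ds, start)

  # Compiled fast path for the DA objective (identical trajectory to the R
  # loop below; see src/lda_eval.cpp). The R loop remains the reference for
  # audited runs and non-DA classifiers.
  if (!audit && cfg$classifier == "da") {
    res <- .tabu_run_da(ds$x, ds$y, lda_stats(ds, cache), S, cfg$beta,
                        cfg$ridge, tenure, params$max_iter_ts)
    if (isTRUE(res$early))
      warning("tabu search stopped early: no admissible move at iteration ",
              res$iterations)
    if (!is.null(cache)) cache$misses <- cache$misses + res$n_fits
    return(list(subset = as.integer(res$subset), f = res$f, rat = res$rat,
                iterations = res$iterations,
                trace = data.frame(iteration = seq_along(res$trace_f),
                                   f = res$trace_f, f_best = res$trace_best)))
  }
  ev <- evaluate_subset(ds, S, cfg, cache)
  f_cur <- ev[["f"]]
  S_star <- S
  f_star <- f_cur
  rat_star <- ev[["rat"]]
  mem <- tabu_memory(ds$m, tenure)
  no_improve <- 0L
  trace_f <- numeric(0)
  trace_best <- numeric(0)
  audit_log <- if (audit) list() else NULL

  while (no_improve < params$max_iter_ts) {
    mem$iter <- mem$iter + 1L
    moves <- enumerate_moves(S, ds$m)
    if (is.null(moves)) break
    n_mv <- nrow(moves)
    neighbors <- vector("list", n_mv)
    for (i in seq_len(n_mv))
      neighbors[[i]] <- apply_move(S, moves$type[i], moves$j_in[i], moves$j_out[i])

    sizes <- lengths(neighbors)
    f_n <- numeric(n_mv)
    nonempty <- sizes > 0L
    if (any(nonempty)) {
      res <- evaluate_subsets(ds, neighbors[nonempty], cfg, cache)
      f_n[nonempty] <- res$f
    }

    entry_tabu <- !is.na(moves$j_in) &
      mem$iter <= mem$vector_out[ifelse(is.na(moves$j_in), 1L, moves$j_in)] + tenure
    exit_tabu <- !is.na(moves$j_out) &
      mem$iter <= mem$vector_in[ifelse(is.na(moves$j_out), 1L, moves$j_out)] + tenure
    tabu <- entry_tabu | exit_tabu
    considered <- !tabu | f_n > f_star

    if (audit) {
      audit_log[[length(audit_log) + 1L]] <- list(
        iter = mem$iter, f_star_before = f_star, S_before = S,
        vector_in = mem$vector_in, vector_out = mem$vector_out,
        moves = data.frame(moves, f = f_n, entry_tabu = entry_tabu,
                           exit_tabu = exit_tabu, tabu = tabu,
                           considered = considered))
    }

    if (!any(considered)) {
      warning("tabu search stopped early: no admissible move at iteration ",
              mem$iter)
      break
    }

    cand <- which(considered)
    best_f <- max(f_n[cand])
    chosen <- draw_one(cand[f_n[cand] == best_f])
    if (audit)
      audit_log[[length(audit_log)]]$chosen <- chosen

    type <- moves$type[chosen]
    j_in <- moves$j_in[chosen]
    j_out <- moves$j_out[chosen]
    S <- neighbors[[chosen]]
    f_cur <- f_n[chosen]
    if (!is.na(j_in)) mem$vector_in[j_in] <- mem$iter
    if (!is.na(j_out)) mem$vector_out[j_out] <- mem$iter

    if (f_cur > f_star) {
      f_star <- f_cur
      S_star <- S
      rat_star <- if (length(S)) res$rat[match(chosen, which(nonempty))] else NA_real_
      no_improve <- 0L
    } else {
      no_improve <- no_improve + 1L
    }
    trace_f <- c(trace_f, f_cur)
    trace_best <- c(trace_best, f_star)
  }

  out <- list(subset = S_star, f = f_star, rat = rat_star,
              iterations = mem$iter,
              trace = data.frame(iteration = seq_along(trace_f),
                                 f = trace_f, f_best = trace_best))
  if (audit) out$audit <- audit_log
  out
}

#' Multistart tabu search feature selection
#'
#' The top-level method: repeatedly build a greedy randomized start
#' ([constructive()]) and improve it with [tabu_search()], keeping the best
#' subset seen. Stops after `max_iter_ms` consecutive starts that fail to
#' improve the incumbent `f_best`. Deterministic given `params$seed` (for
#' the DA classifier, bit-identical across repeated runs).
#'
#' @inheritParams constructive
#' @param cache Optional [evaluation_cache()]; one is created per run when
#'   `NULL`.
#' @param audit Propagate auditing to the construction and tabu phases.
#' @return An object of class `mstabu_result`: list with `best_subset`
#'   (integer indices), `best_feature_names`, `best_f`, `best_rat`,
#'   `iter_best` (start at which the incumbent was found), `starts`,
#'   `evaluations` (classifier fits), `trace` (one row per start:
#'   constructive f, tabu f, running best), and optionally `audit`.
#' @export
#' @examples
#' spec <- synthetic_spec(n = 120, m = 6, r = 2, delta = 2, seed = 3)
#' ds <- normalize_features(generate_synthetic(spec)$dataset)$train
#' res <- multistart_tabu(ds, objective_config(), search_params(seed = 1))
#' res$best_feature_names
multistart_tabu <- function(ds, cfg = objective_config(),
                            params = search_params(), cache = NULL,
                            audit = FALSE) {
  stopifnot(inherits(ds, "fs_dataset"))
  if (anyNA(ds$x)) stop("dataset contains missing cells; clean it first")
  params <- resolve_params(params, ds$m)
  cache <- cache %||% evaluation_cache()

  S_best <- integer(0)
  f_best <- -Inf
  rat_best <- NA_real_
  iter_best <- 0L
  start_i <- 0L
  no_improve <- 0L
  rows <- list()
  audit_log <- if (audit) list() else NULL

  withr::with_seed(params$seed, {
    while (no_improve < params$max_iter_ms) {
      start_i <- start_i + 1L
      cons <- constructive(ds, cfg, params, cache, audit = audit)
      ts <- tabu_search(ds, cfg, cons$subset, params, cache, audit = audit)
      if (ts$f > f_best) {
        f_best <- ts$f
        S_best <- ts$subset
        rat_best <- ts$rat
        iter_best <- start_i
        no_improve <- 0L
      } else {
        no_improve <- no_improve + 1L
      }
      rows[[start_i]] <- data.frame(start = start_i, f_constructive = cons$f,
                                    f_tabu = ts$f, f_best = f_best)
      if (audit)
        audit_log[[start_i]] <- list(constructive = cons$audit, tabu = ts$audit)
    }
  })

  out <- structure(list(
    best_subset = S_best,
    best_feature_names = ds$feature_names[S_best],
    best_f = f_best,
    best_rat = rat_best,
    iter_best = iter_best,
    starts = start_i,
    evaluations = cache$misses,
    trace = do.call(rbind, rows)
  ), class = "mstabu_result")
  if (audit) out$audit <- audit_log
  out
}

#' @export
print.mstabu_result <- function(x, ...) {
  cat(sprintf(
    "<mstabu_result> f_best = %.4f (rat = %.4f), %d feature(s) selected\n",
    x$best_f, x$best_rat, length(x$best_subset)))
  cat("  features:", paste(x$best_feature_names, collapse = ", "), "\n")
  cat(sprintf("  %d start(s), incumbent found at start %d, %s classifier fits\n",
              x$starts, x$iter_best, format(x$evaluations, big.mark = ",")))
  invisible(x)
}

#' Verify local optimality of a subset
#'
#' Sweeps the full add/remove/swap neighborhood of `subset` and reports
#' whether any neighbor has a strictly higher objective — the post-hoc check
#' that a returned solution is a local optimum with respect to `N(S)`.
#'
#' @inheritParams greedy_gains
#' @param subset Subset to check.
#' @return List with `is_local_opt` (logical), `best_neighbor_f`, and `f`.
#' @export
check_local_optimum <- function(ds, subset, cfg = objective_config(),
                                cache = NULL) {
  subset <- resolve_subset(ds, subset)
  f0 <- evaluate_subset(ds, subset, cfg, cache)[["f"]]
  moves <- enumerate_moves(subset, ds$m)
  neigh <- lapply(seq_len(nrow(moves)), function(i)
    apply_move(subset, moves$type[i], moves$j_in[i], moves$j_out[i]))
  sizes <- lengths(neigh)
  f_n <- numeric(length(neigh))
  if (any(sizes > 0L))
    f_n[sizes > 0L] <- evaluate_subsets(ds, neigh[sizes > 0L], cfg, cache)$f
  best <- if (length(f_n)) max(f_n) else -Inf
  list(is_local_opt = best <= f0, best_neighbor_f = best, f = f0)
}
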