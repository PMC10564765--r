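---
title: "Multistart tabu search for wrapper feature selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multistart tabu search for wrapper feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Clinical diagnosis datasets typically record tens of candidate features
(clinical measurements, test results, imaging descriptors) per case, of which
only a few carry diagnostic signal. Wrapper feature selection searches for a
subset `S` of the feature universe `V` (|V| = m) that yields an efficient
classifier: accurate, but also small, because smaller models are cheaper to
measure, easier to interpret, and less prone to noise.

`mstabu` scores a candidate subset with the composite objective

    f(S) = beta * Rat(S) + (1 - beta) * (1 - |S| / m)

where `Rat(S)` is the **resubstitution rate**: the fraction of training cases
correctly classified by a model fitted on the training data restricted to
`S`. The weight `beta` (default 0.99, the customary value for this family of
objectives) trades classifying capacity against parsimony. By convention
`f(∅) = 0`, overriding the formula, so the empty subset never wins and every
feature is a candidate at the start of a construction. `Rat` is deliberately
a training-set rate — optimistic by design; generalization is measured
separately by the cross-validation harness, never by the objective.

## The search

The optimizer is a multistart metaheuristic. Each start has two phases.

**Greedy randomized construction.** Starting from `S = ∅` (objective 0),
each step computes the gain `g(j) = f(S ∪ {j})` for every feature outside
`S`, keeps the improving candidates `L' = {j : g(j) >= f(S)}`, restricts
them to the near-best list `L = {j ∈ L' : g(j) >= gmin + alpha (gmax -
gmin)}` (gmin, gmax over `L'`), and adds a uniform-random member of `L`.
Construction stops when `L'` is empty. `alpha = 1` is fully greedy
(deterministic up to ties); `alpha = 0` samples uniformly from all improving
candidates. Restricting the candidate list to *improving* features at every
`alpha` is what makes the stopping rule (`L' = ∅`) well defined; at
`alpha = 0` the draw is therefore uniform over `L'`, not over all of
`V - S`.

**Tabu search.** From the constructed start, a best-improvement local search
over three move types — add a feature, remove a feature, or swap one inside
for one outside — enumerates the full neighborhood `N(S)` each iteration and
executes the admissible neighbor with the highest `f`, even when that
worsens the current solution. Cycling is suppressed with two per-feature
iteration stamps: `vector_in[j]` (last iteration `j` entered `S`) and
`vector_out[j]` (last iteration `j` left). Re-adding `j` is tabu while
`iter <= vector_out[j] + tenure`; removing `j` is tabu while
`iter <= vector_in[j] + tenure`; a swap is tabu if either of its two halves
is. The **aspiration criterion** overrides tabu status for any neighbor
whose `f` exceeds the best value found so far in this tabu run, so tabu
status can never block an improvement. A run stops after `max_iter_ts`
consecutive iterations without improving the run best.

The multistart driver repeats construct-then-improve, keeping the incumbent
`S_best`, and stops after `max_iter_ms` consecutive starts without
improvement.

## Parameters

| parameter     | default           | meaning                                              |
|---------------|-------------------|------------------------------------------------------|
| `beta`        | 0.99              | objective weight on the resubstitution rate          |
| `alpha`       | 0.99              | RCL greediness; near-greedy with light randomization |
| `tenure`      | `ceiling(m / 2)`  | iterations a reversed move stays forbidden           |
| `max_iter_ts` | `10 * m`          | non-improving tabu iterations before a run stops     |
| `max_iter_ms` | 10                | non-improving starts before the method stops         |

The tenure and iteration caps scale with the number of features `m`, the
size of the decision space: a tenure of `m/2` forbids reversing roughly half
the universe at any time, which suppresses short cycles while leaving the
neighborhood workable, whereas a tenure scaled to the *case* count would
routinely exceed `m` and freeze the search entirely. All parameters remain
directly settable through `search_params()`.

Two comparator choices are deliberately non-strict/strict: a constructive
step accepts `g(j) >= f(S)` (non-strict, so plateau moves can extend a
start), while the aspiration bar and the incumbent update use strictly
greater (`>`), so ties never count as improvement and the
no-improvement stopping counters cannot be reset by plateaus.

## Classifiers

Three classifier kinds stand behind one fit/predict contract:

* **DA** — linear discriminant analysis with pooled within-class covariance
  (denominator `n - 2`) and empirical class priors. This is closed form and
  is the classifier used throughout tuning and testing because the wrapper
  fits it tens of thousands of times per run; the evaluation is compiled,
  with the pooled scatter matrix precomputed once per dataset so each subset
  costs one small linear solve. A singular covariance (e.g. collinear or
  constant features) falls back to a diagonal ridge of `1e-6` with a
  warning. Cases exactly on the decision boundary (score 0) classify
  positive — a measure-zero tie-break that is simply fixed rather than
  randomized.
* **LR** — logistic regression via `stats::glm` (IRLS), predicting positive
  at posterior 0.5. Non-convergence returns the last iterate with a warning.
* **SVM** — linear support vector machine via `e1071::svm`, cost 1,
  predicting by the sign of the decision value.

The wrapper never inspects solver internals, so any deterministic solver
satisfying the contract is interchangeable; `register_classifier()` adds
further kinds. For DA the whole search trajectory is bit-reproducible given
a seed; the compiled tabu loop and the instrumented R loop consume the same
RNG stream with the same arithmetic, so audited runs replay the exact
trajectory of fast runs.

## Evaluation protocol

`run_cv_experiment()` implements the experimental design: stratified k-fold
cross-validation (default k = 10, seeded, per-class fold counts within one).
For each fold the training part is standardized per feature — z-scores with
the population standard deviation, fitted on the training fold only and
applied unchanged to the test fold, so no test information leaks into the
transform (min–max is available as an alternative) — the search runs on the
training fold, the classifier is refitted on the selected subset, and the
held-out fold is scored from its confusion table:

* `ACC = (TP + TN) / total`
* `AUC = (1 + TPR - FPR) / 2` — **a single-table balanced-accuracy form,
  not a ROC-curve integral**. This is intentional and worth emphasizing: it
  is the formula the protocol defines, and it equals ACC and Gmean exactly
  when TPR = TNR.
* `Gmean = sqrt(TPR * TNR)`
* `F1 = 2 TP / (2 TP + FP + FN)`

A fold with no positives (or no negatives) leaves TPR (TNR) undefined; the
metric is reported as `NaN` with a warning and the fold is excluded from
t-test pairings, never silently scored zero. Methods are compared with a
classical paired two-tailed t-test on fold-aligned scores
(`paired_t_test()`), with a three-way verdict at a configurable level
(default 0.05) and explicit handling of zero-variance differences.

## The synthetic benchmark and what it shows

`generate_synthetic()` draws two-class Gaussian data: `r` informative
features whose class means differ by `delta` standard deviations, the rest
pure noise, with configurable imbalance. Class-conditional Gaussians with a
shared covariance are chosen because pooled-covariance DA is Bayes-optimal
there — "the informative subset is the good subset" then holds by
construction, which is what lets an exhaustive oracle
(`exhaustive_best_subset()`, guarded at m ≤ 15, ties broken toward smaller
then lexicographically earlier subsets) serve as ground truth for the
search.

The test suite runs the search against the oracle on instances of n = 300
cases and m = 10 features (3 informative, delta = 2) and audits recovery at
n = 400, m = 30 (4 informative); these sizes keep exhaustive enumeration
and repeated seeded runs at desk scale while leaving the search problem
non-trivial (2^30 subsets in the larger case).

Two honest caveats. First, the generator's features are independent;
real clinical data has correlated blocks, and nothing here demonstrates
behavior under collinearity beyond the ridge fallback. Second, because
`Rat` is a resubstitution rate, a noise feature that lets the training fit
absorb even one extra case raises `f` by `beta/n`, which at the benchmark
sizes exceeds the parsimony cost `(1 - beta)/m` — so the *true* optimum of
`f` includes overfitting noise features, and the search, working correctly,
finds them. The acceptance script measures this directly
(`mean_noise_selected`). This is a property of the objective with
`beta = 0.99`, not a defect of the optimizer: on the same instances the
search matches the exhaustive optimum of `f` almost always. Users who want
leaner subsets should lower `beta` or increase `n` relative to `m`.

## Numerical and design notes

* Feature indices are 1-based throughout, following R convention; all
  user-facing reports use feature names.
* The empty subset is never evaluated by a classifier; its objective is the
  hard-coded convention 0.
* Evaluated subsets are memoized under an order-independent key
  (`evaluation_cache()`); a hit returns the stored value unchanged, and for
  DA a recomputation reproduces the cached value bit for bit.
* Tabu memory is reset at the start of every tabu run; stamps initialize to
  `-(tenure + 1)` so nothing is tabu at iteration 1.
* Ties among best admissible neighbors break uniformly at random from the
  run's RNG stream; ties in the oracle break toward parsimony.
* Degenerate inputs: constant features normalize to all-zeros; a class with
  fewer members than k falls back to unstratified folds with a warning; a
  tabu iteration with no admissible move terminates the run early with a
  warning.

## Limitations

* Binary classification only; no kernel SVMs, no probability calibration.
* The objective is single-criterion; no Pareto view of the
  accuracy/parsimony trade-off.
* Long-term frequency memory, path relinking and other tabu extensions are
  out of scope; the neighborhood is always enumerated in full.
* Resubstitution optimism, discussed above, is inherent to the objective
  definition.
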