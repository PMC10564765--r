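// Fast pooled-covariance linear discriminant analysis for subset evaluation.
// The wrapper search scores thousands of candidate subsets per run, so the
// resubstitution rate for DA is computed here rather than through a generic
// model-fitting interface. The pooled scatter matrix and class means are
// precomputed once per dataset; evaluating a subset is then a submatrix
// solve plus one pass over the cases. Binary only; empirical class priors;
// ties on the decision boundary (score exactly 0) classified positive.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Pooled within-class covariance (denominator max(n-2, 1)) and class means
// over the full feature universe. Entry (a,b) of the pooled matrix restricted
// to a subset equals the pooled covariance computed on that subset alone.
// [[Rcpp::export(name = ".lda_make_stats")]]
List lda_make_stats(const arma::mat& X, const IntegerVector& y) {
  arma::uvec y1(y.size());
  for (int i = 0; i < y.size(); ++i) y1[i] = static_cast<arma::uword>(y[i]);
  const arma::uvec i1 = arma::find(y1 == 1);
  const arma::uvec i0 = arma::find(y1 == 0);
  if (i1.n_elem < 1 || i0.n_elem < 1)
    stop("both classes must be present");
  const arma::mat X1 = X.rows(i1);
  const arma::mat X0 = X.rows(i0);
  const arma::rowvec mu1 = arma::mean(X1, 0);
  const arma::rowvec mu0 = arma::mean(X0, 0);
  arma::mat C1 = X1.each_row() - mu1;
  arma::mat C0 = X0.each_row() - mu0;
  const double denom = std::max(static_cast<double>(X.n_rows) - 2.0, 1.0);
  arma::mat Sp = (C1.t() * C1 + C0.t() * C0) / denom;
  return List::create(_["Sp"] = Sp,
                      _["mu1"] = NumericVector(mu1.begin(), mu1.end()),
                      _["mu0"] = NumericVector(mu0.begin(), mu0.end()),
                      _["n1"] = static_cast<double>(i1.n_elem),
                      _["n0"] = static_cast<double>(i0.n_elem));
}

// Linear decision rule (w, b) for the subset idx (0-based): predict positive
// iff x' w + b >= 0. Singular pooled covariance falls back to a diagonal
// ridge.
static bool lda_weights_pre(const arma::mat& Sp, const arma::vec& mu1,
                            const arma::vec& mu0, double n1, double n0,
                            const arma::uvec& idx, double ridge,
                            arma::vec& w, double& b, bool& used_ridge) {
  arma::mat S = Sp.submat(idx, idx);
  const arma::vec d = mu1.elem(idx) - mu0.elem(idx);
  used_ridge = false;
  bool ok = arma::solve(w, S, d, arma::solve_opts::no_approx);
  if (!ok || !w.is_finite()) {
    S.diag() += ridge;
    ok = arma::solve(w, S, d, arma::solve_opts::no_approx);
    used_ridge = true;
    if (!ok || !w.is_finite()) return false;
  }
  b = -0.5 * arma::dot(mu1.elem(idx) + mu0.elem(idx), w) + std::log(n1 / n0);
  return true;
}

static arma::uvec as_uvec0(const IntegerVector& idx1) {
  arma::uvec out(idx1.size());
  for (int i = 0; i < idx1.size(); ++i)
    out[i] = static_cast<arma::uword>(idx1[i] - 1);
  return out;
}

// Resubstitution rate of each subset in `subsets` (1-based index vectors).
// [[Rcpp::export(name = ".lda_rat_batch")]]
NumericVector lda_rat_batch(const arma::mat& X, const IntegerVector& y,
                            const List& stats, const List& subsets,
                            double ridge) {
  const arma::mat Sp = as<arma::mat>(stats["Sp"]);
  const arma::vec mu1 = as<arma::vec>(stats["mu1"]);
  const arma::vec mu0 = as<arma::vec>(stats["mu0"]);
  const double n1 = as<double>(stats["n1"]);
  const double n0 = as<double>(stats["n0"]);
  const int n = X.n_rows;
  IntegerVector yy(y);

  const int nsub = subsets.size();
  NumericVector out(nsub);
  arma::vec w;
  double b = 0.0;
  bool used_ridge = false;
  for (int s = 0; s < nsub; ++s) {
    IntegerVector idx1 = subsets[s];
    const arma::uvec idx = as_uvec0(idx1);
    if (!lda_weights_pre(Sp, mu1, mu0, n1, n0, idx, ridge, w, b, used_ridge)) {
      out[s] = NA_REAL;
      continue;
    }
    const arma::vec score = X.cols(idx) * w + b;
    int correct = 0;
    for (int i = 0; i < n; ++i) {
      const int pred = (score[i] >= 0.0) ? 1 : 0;
      if (pred == yy[i]) ++correct;
    }
    out[s] = static_cast<double>(correct) / static_cast<double>(n);
  }
  return out;
}

// Fitted decision rule for one subset, for the classifier fit/predict
// contract.
// [[Rcpp::export(name = ".lda_fit")]]
List lda_fit(const arma::mat& X, const IntegerVector& y,
             const IntegerVector& idx, double ridge) {
  List stats = lda_make_stats(X, y);
  const arma::mat Sp = as<arma::mat>(stats["Sp"]);
  const arma::vec mu1 = as<arma::vec>(stats["mu1"]);
  const arma::vec mu0 = as<arma::vec>(stats["mu0"]);
  arma::vec w;
  double b = 0.0;
  bool used_ridge = false;
  if (!lda_weights_pre(Sp, mu1, mu0, as<double>(stats["n1"]),
                       as<double>(stats["n0"]), as_uvec0(idx), ridge,
                       w, b, used_ridge))
    stop("LDA fit failed: degenerate class structure");
  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["b"] = b,
                      _["used_ridge"] = used_ridge);
}

// ---------------------------------------------------------------------------
// Compiled tabu-search inner loop for the DA objective.
//
// Semantically identical to the R implementation in R/search.R (same
// neighborhood enumeration order, same tabu/aspiration logic, same
// tie-breaking draw from R's RNG stream, same double arithmetic for the
// objective), so a run with a given seed produces the same trajectory on
// either path. Used automatically by tabu_search() when the classifier is
// DA and no audit is requested; the R path remains the reference for
// instrumented runs and plugin classifiers.

#include <map>
#include <vector>

namespace {

struct DaEval {
  const arma::mat& X;
  const IntegerVector& y;
  const arma::mat Sp;
  const arma::vec mu1, mu0;
  const double n1, n0, ridge, beta;
  const int m;
  std::map<std::vector<int>, double> cache;
  long n_fits = 0;

  DaEval(const arma::mat& X_, const IntegerVector& y_, const List& stats,
         double ridge_, double beta_)
      : X(X_), y(y_), Sp(as<arma::mat>(stats["Sp"])),
        mu1(as<arma::vec>(stats["mu1"])), mu0(as<arma::vec>(stats["mu0"])),
        n1(as<double>(stats["n1"])), n0(as<double>(stats["n0"])),
        ridge(ridge_), beta(beta_), m(static_cast<int>(X_.n_cols)) {}

  double rat(const std::vector<int>& sub) {
    auto it = cache.find(sub);
    if (it != cache.end()) return it->second;
    arma::uvec idx(sub.size());
    for (size_t i = 0; i < sub.size(); ++i)
      idx[i] = static_cast<arma::uword>(sub[i] - 1);
    arma::vec w;
    double b = 0.0;
    bool used_ridge = false;
    double r = NA_REAL;
    if (lda_weights_pre(Sp, mu1, mu0, n1, n0, idx, ridge, w, b, used_ridge)) {
      const arma::vec score = X.cols(idx) * w + b;
      int correct = 0;
      for (arma::uword i = 0; i < score.n_elem; ++i) {
        const int pred = (score[i] >= 0.0) ? 1 : 0;
        if (pred == y[i]) ++correct;
      }
      r = static_cast<double>(correct) / static_cast<double>(X.n_rows);
    }
    ++n_fits;
    cache.emplace(sub, r);
    return r;
  }

  // identical arithmetic to objective_f() in R
  double f(const std::vector<int>& sub) {
    const int size = static_cast<int>(sub.size());
    if (size == 0) return 0.0;
    return beta * rat(sub) +
           (1.0 - beta) * (1.0 - static_cast<double>(size) /
                                     static_cast<double>(m));
  }
};

// one uniform draw per call, matching draw_one() in R
inline int draw_index(int k) {
  int pick = static_cast<int>(unif_rand() * k);
  if (pick >= k) pick = k - 1;
  return pick;
}

}  // namespace

// [[Rcpp::export(name = ".tabu_run_da")]]
List tabu_run_da(const arma::mat& X, const IntegerVector& y, const List& stats,
                 const IntegerVector& start, double beta, double ridge,
                 int tenure, int max_iter_ts) {
  const int m = static_cast<int>(X.n_cols);
  DaEval ev(X, y, stats, ridge, beta);

  std::vector<int> S(start.begin(), start.end());
  std::sort(S.begin(), S.end());
  double f_cur = ev.f(S);
  std::vector<int> S_star = S;
  double f_star = f_cur;
  double rat_star = S.empty() ? NA_REAL : ev.rat(S);

  std::vector<int> vin(m, -(tenure + 1)), vout(m, -(tenure + 1));
  int iter = 0, no_improve = 0;
  bool early = false;
  std::vector<double> trace_f, trace_best;

  // move table rebuilt per iteration; order matches enumerate_moves():
  // adds (ascending), removes (S ascending), swaps (j_in outer ascending,
  // j_out inner ascending)
  std::vector<int> mv_in, mv_out;  // 0 = none
  std::vector<std::vector<int>> neigh;
  std::vector<double> f_n;
  std::vector<char> considered;

  while (no_improve < max_iter_ts) {
    ++iter;
    std::vector<int> outside;
    outside.reserve(m);
    {
      std::vector<char> inS(m + 1, 0);
      for (int j : S) inS[j] = 1;
      for (int j = 1; j <= m; ++j)
        if (!inS[j]) outside.push_back(j);
    }

    mv_in.clear(); mv_out.clear(); neigh.clear();
    for (int j : outside) { mv_in.push_back(j); mv_out.push_back(0); }
    for (int j : S) { mv_in.push_back(0); mv_out.push_back(j); }
    for (int ji : outside)
      for (int jo : S) { mv_in.push_back(ji); mv_out.push_back(jo); }

    const size_t n_mv = mv_in.size();
    if (n_mv == 0) break;
    neigh.resize(n_mv);
    f_n.assign(n_mv, 0.0);
    considered.assign(n_mv, 0);

    for (size_t i = 0; i < n_mv; ++i) {
      std::vector<int> nb;
      nb.reserve(S.size() + 1);
      for (int j : S)
        if (j != mv_out[i]) nb.push_back(j);
      if (mv_in[i] != 0) {
        nb.push_back(mv_in[i]);
        std::sort(nb.begin(), nb.end());
      }
      f_n[i] = ev.f(nb);
      neigh[i] = std::move(nb);
    }

    bool any_considered = false;
    for (size_t i = 0; i < n_mv; ++i) {
      const bool entry_tabu =
          mv_in[i] != 0 && iter <= vout[mv_in[i] - 1] + tenure;
      const bool exit_tabu =
          mv_out[i] != 0 && iter <= vin[mv_out[i] - 1] + tenure;
      considered[i] = (!(entry_tabu || exit_tabu) || f_n[i] > f_star) ? 1 : 0;
      if (considered[i]) any_considered = true;
    }
    if (!any_considered) { early = true; break; }

    double best_f = R_NegInf;
    for (size_t i = 0; i < n_mv; ++i)
      if (considered[i] && f_n[i] > best_f) best_f = f_n[i];
    std::vector<int> ties;
    for (size_t i = 0; i < n_mv; ++i)
      if (considered[i] && f_n[i] == best_f) ties.push_back(static_cast<int>(i));
    const int chosen = ties[draw_index(static_cast<int>(ties.size()))];

    S = neigh[chosen];
    f_cur = f_n[chosen];
    if (mv_in[chosen] != 0) vin[mv_in[chosen] - 1] = iter;
    if (mv_out[chosen] != 0) vout[mv_out[chosen] - 1] = iter;

    if (f_cur > f_star) {
      f_star = f_cur;
      S_star = S;
      rat_star = S.empty() ? NA_REAL : ev.rat(S);
      no_improve = 0;
    } else {
      ++no_improve;
    }
    trace_f.push_back(f_cur);
    trace_best.push_back(f_star);
  }

  return List::create(
      _["subset"] = IntegerVector(S_star.begin(), S_star.end()),
      _["f"] = f_star, _["rat"] = rat_star, _["iterations"] = iter,
      _["trace_f"] = NumericVector(trace_f.begin(), trace_f.end()),
      _["trace_best"] = NumericVector(trace_best.begin(), trace_best.end()),
      _["n_fits"] = static_cast<double>(ev.n_fits),
      _["early"] = early);
}
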