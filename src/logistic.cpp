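#include <RcppArmadillo.h>
#include <array>
#include <cstdint>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// Penalized Newton maximum-likelihood logistic fit. `ridge` > 0 adds an L2
// penalty on the non-intercept coefficients; the unpenalized fit is
// attempted first by the callers and this is the numerical fallback.
// Returns false when a step fails or the coefficients diverge (separable
// data), leaving `beta` at its last finite value.
bool irls_fit(const arma::mat& X, const arma::vec& y, double ridge,
              arma::vec& beta, int maxit = 25, double tol = 1e-10) {
  const arma::uword p = X.n_cols;
  if (!beta.is_finite() || beta.n_elem != p) beta = arma::zeros(p);
  arma::vec pen(p, arma::fill::value(ridge));
  pen(0) = 0.0; // intercept unpenalized
  // Already perfectly saturated at the start (warm start on separable
  // data): no iteration can change the predictions.
  {
    arma::vec mu0 = 1.0 / (1.0 + arma::exp(-(X * beta)));
    if (arma::all(arma::abs(y - mu0) < 1e-9)) return true;
  }
  double dev_old = arma::datum::inf;
  for (int it = 0; it < maxit; ++it) {
    arma::vec eta = X * beta;
    arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
    arma::vec w = mu % (1.0 - mu);
    w = arma::clamp(w, 1e-10, 1.0);
    arma::mat XtW = X.t();
    XtW.each_row() %= w.t();
    arma::mat H = XtW * X;
    H.diag() += pen;
    arma::vec grad = X.t() * (y - mu) - pen % beta;
    arma::vec step;
    if (!arma::solve(step, H, grad, arma::solve_opts::no_approx))
      return false;
    arma::vec beta_new = beta + step;
    if (!beta_new.is_finite()) return false;
    beta = beta_new;
    // Separable data: coefficients this large mean every fitted
    // probability is fully saturated; further iteration cannot change the
    // predictions, so stop here (mirrors glm's behaviour of returning the
    // diverged fit rather than failing).
    if (arma::abs(beta).max() > 1e8) return true;
    arma::vec eta_n = X * beta;
    arma::vec mu_n = 1.0 / (1.0 + arma::exp(-eta_n));
    if (arma::all(arma::abs(y - mu_n) < 1e-9)) return true; // separated
    mu_n = arma::clamp(mu_n, 1e-12, 1.0 - 1e-12);
    double dev = -2.0 * arma::accu(y % arma::log(mu_n) +
                                   (1.0 - y) % arma::log(1.0 - mu_n));
    if (arma::abs(step).max() < 1e-8 ||
        std::abs(dev_old - dev) < tol * (std::abs(dev) + 0.1))
      return true;
    dev_old = dev;
  }
  return beta.is_finite();
}

// Fit with unpenalized ML first; fall back to a tiny ridge (1e-8) when the
// Newton steps fail numerically (singular system, overflow). `init`
// warm-starts the iteration (the converged estimate does not depend on it).
arma::vec fit_with_fallback(const arma::mat& X, const arma::vec& y,
                            bool& used_ridge, const arma::vec* init = 0) {
  arma::vec beta = init ? *init : arma::zeros(X.n_cols);
  used_ridge = false;
  bool ok = irls_fit(X, y, 0.0, beta);
  if (!ok || !beta.is_finite()) {
    beta = arma::zeros(X.n_cols);
    used_ridge = true;
    irls_fit(X, y, 1e-8, beta, 30);
    if (!beta.is_finite())
      Rcpp::stop("logistic fit failed even with ridge fallback");
  }
  return beta;
}

// Standardize columns of `tr` by its own mean/sd; apply to `te` rows.
// Constant columns get sd 1 so they zero out after centring.
void standardize(arma::mat& tr, arma::mat& te, arma::rowvec& m,
                 arma::rowvec& s) {
  m = arma::mean(tr, 0);
  s = arma::stddev(tr, 0, 0); // sample sd (n-1)
  s.elem(arma::find(s <= 0)).fill(1.0);
  tr.each_row() -= m;
  tr.each_row() /= s;
  te.each_row() -= m;
  te.each_row() /= s;
}

// Tie-aware rank-based AUC (Mann-Whitney normalization).
double auc_rank(const arma::vec& prob, const arma::vec& y) {
  const arma::uword n = prob.n_elem;
  arma::uvec ord = arma::stable_sort_index(prob);
  arma::vec rank(n);
  arma::uword i = 0;
  while (i < n) {
    arma::uword j = i;
    while (j + 1 < n && prob(ord(j + 1)) == prob(ord(i))) ++j;
    double avg = (static_cast<double>(i) + static_cast<double>(j)) / 2.0 + 1.0;
    for (arma::uword k = i; k <= j; ++k) rank(ord(k)) = avg;
    i = j + 1;
  }
  double n1 = arma::accu(y), n0 = static_cast<double>(n) - n1;
  if (n1 == 0 || n0 == 0) return NA_REAL;
  double rsum = arma::accu(rank.elem(arma::find(y == 1.0)));
  return (rsum - n1 * (n1 + 1.0) / 2.0) / (n1 * n0);
}

struct LoocvOut {
  arma::vec prob;      // held-out probabilities, one per case
  arma::mat coef;      // n x (p+1): per-fold [intercept, betas]
  bool any_ridge;
};

LoocvOut loocv_core(const arma::mat& X, const arma::vec& y) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  LoocvOut out;
  out.prob.set_size(n);
  out.coef.set_size(n, p + 1);
  out.any_ridge = false;
  // Warm start for the folds: the full-data fit on full-data
  // standardization. Newton converges to the fold MLE regardless of the
  // start, so held-out results are unaffected.
  arma::vec warm;
  {
    arma::mat Xs = X, dummy(0, p);
    arma::rowvec m, s;
    standardize(Xs, dummy, m, s);
    arma::mat D = arma::join_rows(arma::ones(n), Xs);
    bool ur = false;
    warm = fit_with_fallback(D, y, ur);
  }
  arma::uvec all = arma::regspace<arma::uvec>(0, n - 1);
  for (arma::uword i = 0; i < n; ++i) {
    arma::uvec tr_idx = all.elem(arma::find(all != i));
    arma::mat Xtr = X.rows(tr_idx);
    arma::mat Xte = X.row(i);
    arma::vec ytr = y.elem(tr_idx);
    if (arma::all(ytr == 0.0) || arma::all(ytr == 1.0))
      Rcpp::stop("degenerate LOOCV fold: training fold has a single class");
    arma::rowvec m, s;
    standardize(Xtr, Xte, m, s);
    arma::mat Dtr = arma::join_rows(arma::ones(n - 1), Xtr);
    bool used_ridge = false;
    arma::vec beta = fit_with_fallback(Dtr, ytr, used_ridge, &warm);
    out.any_ridge = out.any_ridge || used_ridge;
    double eta = beta(0) + arma::dot(Xte.row(0), beta.subvec(1, p));
    out.prob(i) = 1.0 / (1.0 + std::exp(-eta));
    out.coef.row(i) = beta.t();
  }
  return out;
}

} // namespace

// [[Rcpp::export(name = ".logisticFitCpp")]]
NumericVector logistic_fit_cpp(NumericMatrix Xr, NumericVector yr) {
  arma::mat X(Xr.begin(), Xr.nrow(), Xr.ncol(), false);
  arma::vec y(yr.begin(), yr.size(), false);
  arma::mat D = arma::join_rows(arma::ones(X.n_rows), X);
  bool used_ridge = false;
  arma::vec beta = fit_with_fallback(D, y, used_ridge);
  NumericVector out(beta.begin(), beta.end());
  out.attr("ridge") = used_ridge;
  return out;
}

// [[Rcpp::export(name = ".loocvLogisticCpp")]]
List loocv_logistic_cpp(NumericMatrix Xr, NumericVector yr) {
  arma::mat X(Xr.begin(), Xr.nrow(), Xr.ncol(), false);
  arma::vec y(yr.begin(), yr.size(), false);
  LoocvOut res = loocv_core(X, y);
  return List::create(
      _["prob"] = NumericVector(res.prob.begin(), res.prob.end()),
      _["coef"] = wrap(res.coef), _["ridge_used"] = res.any_ridge,
      _["auc"] = auc_rank(res.prob, y));
}

// Exhaustive subset scan: evaluates every non-empty subset of the columns of
// X (bitmask order, subject to the size and count caps) by LOOCV AUC.
// Returns one row per evaluated subset: mask, auc, f1, accuracy.
// [[Rcpp::export(name = ".bestSubsetCpp")]]
NumericMatrix best_subset_cpp(NumericMatrix Xr, NumericVector yr,
                              int maxSubsetSize, double maxSubsets) {
  arma::mat X(Xr.begin(), Xr.nrow(), Xr.ncol(), false);
  arma::vec y(yr.begin(), yr.size(), false);
  const int p = static_cast<int>(X.n_cols);
  if (p > 30) stop("too many candidate covariates for exhaustive search");
  const uint64_t total = (1ULL << p) - 1ULL;
  std::vector<std::array<double, 4>> rows;
  uint64_t evaluated = 0;
  for (uint64_t mask = 1; mask <= total; ++mask) {
    int sz = 0;
    for (int j = 0; j < p; ++j)
      if (mask & (1ULL << j)) ++sz;
    if (sz > maxSubsetSize) continue;
    if (static_cast<double>(evaluated) >= maxSubsets) break;
    arma::uvec cols(sz);
    int c = 0;
    for (int j = 0; j < p; ++j)
      if (mask & (1ULL << j)) cols(c++) = j;
    arma::mat Xs = X.cols(cols);
    LoocvOut res = loocv_core(Xs, y);
    double auc = auc_rank(res.prob, y);
    double tp = 0, fp = 0, tn = 0, fn = 0;
    for (arma::uword i = 0; i < y.n_elem; ++i) {
      bool pred = res.prob(i) > 0.5;
      if (pred && y(i) == 1) ++tp;
      else if (pred && y(i) == 0) ++fp;
      else if (!pred && y(i) == 0) ++tn;
      else ++fn;
    }
    double f1 = (2 * tp + fp + fn) > 0 ? 2 * tp / (2 * tp + fp + fn) : 0.0;
    double acc = (tp + tn) / static_cast<double>(y.n_elem);
    rows.push_back({static_cast<double>(mask), auc, f1, acc});
    ++evaluated;
    if (evaluated % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix out(static_cast<int>(rows.size()), 4);
  for (size_t i = 0; i < rows.size(); ++i)
    for (int j = 0; j < 4; ++j) out(i, j) = rows[i][j];
  colnames(out) = CharacterVector::create("mask", "auc", "f1", "accuracy");
  return out;
}
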