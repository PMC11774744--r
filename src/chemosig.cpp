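// Numerical core: IRLS logistic regression with Wald statistics, ROC AUC
// by the Mann-Whitney rank formulation, the repeated-CV AUC loop used by
// the beam search, and the exact permutation distribution for small-sample
// Spearman p-values. Kept in C++ because the signature search refits
// 10^4-10^6 logistic models per run.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct IrlsResult {
  arma::vec beta;
  arma::vec se;
  bool converged;
  bool separation;
  bool singular;
  double deviance;
};

static IrlsResult irls_logistic(const arma::mat& X, const arma::vec& y,
                                int maxit = 25, double tol = 1e-8) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  IrlsResult res;
  res.beta = arma::zeros(p);
  res.se = arma::vec(p, arma::fill::value(NA_REAL));
  res.converged = false;
  res.separation = false;
  res.singular = false;

  // glm-style start: mu from the data, eta = logit(mu)
  arma::vec mu = (y + 0.5) / 2.0;
  arma::vec eta = arma::log(mu / (1.0 - mu));
  double dev_old = R_PosInf;
  arma::mat XtWX;

  for (int it = 0; it < maxit; ++it) {
    arma::vec w = mu % (1.0 - mu);
    w.transform([](double v) { return v < 1e-10 ? 1e-10 : v; });
    arma::vec z = eta + (y - mu) / w;
    arma::mat Xw = X.each_col() % w;
    XtWX = X.t() * Xw;
    arma::vec Xtz = Xw.t() * z;
    arma::vec beta_new;
    bool ok = arma::solve(beta_new, XtWX, Xtz,
                          arma::solve_opts::no_approx);
    if (!ok || !beta_new.is_finite()) {
      res.singular = true;
      return res;
    }
    res.beta = beta_new;
    eta = X * res.beta;
    mu = 1.0 / (1.0 + arma::exp(-eta));
    mu.transform([](double v) {
      if (v < 1e-12) return 1e-12;
      if (v > 1.0 - 1e-12) return 1.0 - 1e-12;
      return v;
    });
    double dev = 0.0;
    for (arma::uword i = 0; i < n; ++i)
      dev -= 2.0 * (y[i] * std::log(mu[i]) +
                    (1.0 - y[i]) * std::log(1.0 - mu[i]));
    if (std::fabs(dev - dev_old) / (std::fabs(dev) + 0.1) < tol) {
      res.converged = true;
      res.deviance = dev;
      break;
    }
    dev_old = dev;
    res.deviance = dev;
  }
  res.separation = arma::any(mu < 1e-9) || arma::any(mu > 1.0 - 1e-9);
  arma::mat cov;
  if (arma::inv_sympd(cov, XtWX))
    res.se = arma::sqrt(cov.diag());
  else
    res.singular = true;
  return res;
}

// Maximum-likelihood logistic fit. X must already contain the intercept
// column. Returns coefficients, Wald SEs (observed information), flags.
// [[Rcpp::export]]
List cpp_fit_logistic(const arma::mat& X, const arma::vec& y) {
  IrlsResult r = irls_logistic(X, y);
  return List::create(
    _["coefficients"] = NumericVector(r.beta.begin(), r.beta.end()),
    _["se"] = NumericVector(r.se.begin(), r.se.end()),
    _["converged"] = r.converged,
    _["separation"] = r.separation,
    _["singular"] = r.singular,
    _["deviance"] = r.deviance);
}

static double auc_rank(const arma::vec& scores, const arma::vec& labels) {
  const arma::uword n = scores.n_elem;
  arma::uvec ord = arma::sort_index(scores);
  arma::vec ranks(n);
  arma::uword i = 0;
  while (i < n) {
    arma::uword j = i;
    while (j + 1 < n && scores[ord[j + 1]] == scores[ord[i]]) ++j;
    double mid = (static_cast<double>(i) + static_cast<double>(j)) / 2.0 + 1.0;
    for (arma::uword k = i; k <= j; ++k) ranks[ord[k]] = mid;
    i = j + 1;
  }
  double n1 = arma::accu(labels), rsum = 0.0;
  double n0 = static_cast<double>(n) - n1;
  if (n1 == 0 || n0 == 0) return NA_REAL;
  for (arma::uword k = 0; k < n; ++k)
    if (labels[k] > 0.5) rsum += ranks[k];
  return (rsum - n1 * (n1 + 1.0) / 2.0) / (n1 * n0);
}

// ROC AUC, Mann-Whitney formulation with ties counted 1/2.
// [[Rcpp::export]]
double cpp_auc(const arma::vec& scores, const arma::vec& labels) {
  return auc_rank(scores, labels);
}

// Mean held-out AUC over repeats x folds. X is samples x genes (no
// intercept; one is added internally); folds is an n x repeats integer
// matrix of fold ids in 1..k. Folds where the fit is singular or the
// held-out part is single-class are skipped.
static double cv_auc_impl(const arma::mat& Xsub, const arma::vec& y,
                          const arma::imat& folds);

// [[Rcpp::export]]
double cpp_cv_auc(const arma::mat& X, const arma::vec& y,
                  const arma::imat& folds) {
  return cv_auc_impl(X, y, folds);
}

static double cv_auc_impl(const arma::mat& Xsub, const arma::vec& y,
                          const arma::imat& folds) {
  double total = 0.0;
  int counted = 0;
  for (arma::uword r = 0; r < folds.n_cols; ++r) {
    int k = folds.col(r).max();
    for (int f = 1; f <= k; ++f) {
      arma::uvec test = arma::find(folds.col(r) == f);
      arma::uvec train = arma::find(folds.col(r) != f);
      if (test.n_elem == 0 || train.n_elem <= Xsub.n_cols + 1) continue;
      arma::vec ytr = y.elem(train), yte = y.elem(test);
      if (arma::accu(yte) == 0 || arma::accu(yte) == yte.n_elem) continue;
      if (arma::accu(ytr) == 0 || arma::accu(ytr) == ytr.n_elem) continue;
      arma::mat Xtr(train.n_elem, Xsub.n_cols + 1, arma::fill::ones);
      Xtr.cols(1, Xsub.n_cols) = Xsub.rows(train);
      IrlsResult fit = irls_logistic(Xtr, ytr);
      if (fit.singular) continue;
      arma::mat Xte(test.n_elem, Xsub.n_cols + 1, arma::fill::ones);
      Xte.cols(1, Xsub.n_cols) = Xsub.rows(test);
      arma::vec sc = Xte * fit.beta;
      double a = auc_rank(sc, yte);
      if (!ISNAN(a)) { total += a; ++counted; }
    }
  }
  return counted ? total / counted : NA_REAL;
}

// One full beam-search step over every survivor x unused-gene extension:
// deduplicates gene sets (a set is accepted as soon as one parent order
// passes the gate), fits each candidate once, applies the significance
// gates, and scores the gated candidates by repeated-CV AUC. Survivor
// and pool-gene indices are 1-based. Ranking and the keep-fraction cut
// stay on the R side.
// [[Rcpp::export]]
List cpp_beam_step(const arma::mat& X, const arma::vec& y,
                   const List& survivors, const arma::imat& folds,
                   double pNew, double pRetained) {
  const int nPool = X.n_cols;
  struct CachedFit {
    bool singular = false, converged = false, separation = false;
    double intercept = 0.0;
    std::vector<double> beta, p;  // aligned with the sorted key
  };
  std::map<std::vector<int>, CachedFit> fits;
  std::set<std::vector<int>> accepted, tried;
  long raw = 0;

  std::vector<std::vector<int>> surv(survivors.size());
  for (R_xlen_t i = 0; i < survivors.size(); ++i) {
    IntegerVector v = survivors[i];
    surv[i] = std::vector<int>(v.begin(), v.end());
  }

  struct Cand {
    std::vector<int> idx;
    std::vector<double> coef, p;
    double intercept, trainAuc, cvAuc;
  };
  std::vector<Cand> cands;

  for (const auto& s : surv) {
    std::set<int> inSet(s.begin(), s.end());
    for (int g = 1; g <= nPool; ++g) {
      if (inSet.count(g)) continue;
      ++raw;
      std::vector<int> key(s);
      key.push_back(g);
      std::sort(key.begin(), key.end());
      tried.insert(key);
      if (accepted.count(key)) continue;

      auto it = fits.find(key);
      if (it == fits.end()) {
        CachedFit cf;
        arma::uvec cols(key.size());
        for (size_t j = 0; j < key.size(); ++j) cols[j] = key[j] - 1;
        arma::mat Xd(X.n_rows, key.size() + 1, arma::fill::ones);
        Xd.cols(1, key.size()) = X.cols(cols);
        IrlsResult fr = irls_logistic(Xd, y);
        cf.singular = fr.singular;
        cf.converged = fr.converged;
        cf.separation = fr.separation;
        if (!fr.singular) {
          cf.intercept = fr.beta[0];
          cf.beta.resize(key.size());
          cf.p.resize(key.size());
          for (size_t j = 0; j < key.size(); ++j) {
            cf.beta[j] = fr.beta[j + 1];
            double z = fr.beta[j + 1] / fr.se[j + 1];
            cf.p[j] = 2.0 * R::pnorm(-std::fabs(z), 0.0, 1.0, 1, 0);
          }
        }
        it = fits.emplace(key, std::move(cf)).first;
      }
      const CachedFit& cf = it->second;
      if (cf.singular || !cf.converged || cf.separation) continue;

      // gate for this parent order: new gene g at pNew, others at pRetained
      bool pass = true;
      for (size_t j = 0; j < key.size() && pass; ++j) {
        double gate = (key[j] == g) ? pNew : pRetained;
        if (!(cf.p[j] < gate) || !std::isfinite(cf.p[j])) pass = false;
      }
      if (!pass) continue;
      accepted.insert(key);

      // emit in addition order (survivor order, then g)
      Cand cd;
      cd.idx = s;
      cd.idx.push_back(g);
      cd.coef.resize(cd.idx.size());
      cd.p.resize(cd.idx.size());
      for (size_t j = 0; j < cd.idx.size(); ++j) {
        size_t pos = std::lower_bound(key.begin(), key.end(), cd.idx[j]) -
          key.begin();
        cd.coef[j] = cf.beta[pos];
        cd.p[j] = cf.p[pos];
      }
      arma::uvec cols(key.size());
      for (size_t j = 0; j < key.size(); ++j) cols[j] = key[j] - 1;
      arma::mat Xsub = X.cols(cols);
      arma::vec betaSorted(cf.beta);
      arma::vec sc = cf.intercept + Xsub * betaSorted;
      cd.intercept = cf.intercept;
      cd.trainAuc = auc_rank(sc, y);
      cd.cvAuc = cv_auc_impl(Xsub, y, folds);
      cands.push_back(std::move(cd));
    }
  }
  const R_xlen_t nOut = cands.size();
  List outIdx(nOut), outCoef(nOut), outP(nOut);
  NumericVector outIntercept(nOut), outTrain(nOut), outCv(nOut);
  for (R_xlen_t i = 0; i < nOut; ++i) {
    const Cand& cd = cands[i];
    outIdx[i] = IntegerVector(cd.idx.begin(), cd.idx.end());
    outCoef[i] = NumericVector(cd.coef.begin(), cd.coef.end());
    outP[i] = NumericVector(cd.p.begin(), cd.p.end());
    outIntercept[i] = cd.intercept;
    outTrain[i] = cd.trainAuc;
    outCv[i] = cd.cvAuc;
  }
  return List::create(
    _["idx"] = outIdx, _["coef"] = outCoef, _["p"] = outP,
    _["intercept"] = outIntercept,
    _["trainAuc"] = outTrain,
    _["cvAuc"] = outCv,
    _["raw"] = static_cast<double>(raw),
    _["uniqueTried"] = static_cast<double>(tried.size()),
    _["gated"] = static_cast<double>(nOut));
}

// Exact permutation distribution of T = sum_i a2[i] * b2[perm(i)] over all
// permutations, for doubled mid-ranks a2, b2 (integers), n <= 10. Returns
// counts indexed by T = 0..Tmax. Dynamic programming over bitmasks of the
// b-values already used.
// [[Rcpp::export]]
NumericVector cpp_spearman_perm_dist(const IntegerVector& a2,
                                     const IntegerVector& b2) {
  const int n = a2.size();
  if (n != b2.size()) stop("rank vectors must have equal length");
  if (n < 2 || n > 10) stop("exact permutation distribution needs 2 <= n <= 10");
  std::vector<int> as(a2.begin(), a2.end()), bs(b2.begin(), b2.end());
  std::sort(as.begin(), as.end());
  std::sort(bs.begin(), bs.end());
  long tmax = 0;
  for (int i = 0; i < n; ++i) tmax += static_cast<long>(as[i]) * bs[i];
  const int full = (1 << n) - 1;
  const size_t width = static_cast<size_t>(tmax) + 1;
  std::vector<double> dp(static_cast<size_t>(full + 1) * width, 0.0);
  dp[0] = 1.0;
  for (int mask = 0; mask < full; ++mask) {
    const int pos = __builtin_popcount(mask);  // next a-index to assign
    const double* row = &dp[static_cast<size_t>(mask) * width];
    bool any = false;
    for (size_t t = 0; t < width; ++t) if (row[t] != 0.0) { any = true; break; }
    if (!any) continue;
    for (int j = 0; j < n; ++j) {
      if (mask & (1 << j)) continue;
      const long add = static_cast<long>(a2[pos]) * b2[j];
      double* nrow = &dp[static_cast<size_t>(mask | (1 << j)) * width];
      for (size_t t = 0; t < width; ++t)
        if (row[t] != 0.0) nrow[t + add] += row[t];
    }
  }
  const double* last = &dp[static_cast<size_t>(full) * width];
  return NumericVector(last, last + width);
}
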