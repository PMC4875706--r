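// Core numerics: basis-convolved design matrices, penalized Bernoulli GLM
// solvers (Newton for the smooth L2 objective, FISTA for L1/group lasso),
// fixed-metric refits for likelihood-ratio null models, and the recurrent
// GLM network simulator. All objectives are MAXIMIZED: ll - eta * Reg.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double LAM_LO = -30.0;
static const double LAM_HI = 12.0;

// per-observation log-likelihood, score and curvature weight for one bin
// link: 0 = logistic, 1 = complementary log-log
static inline void bin_terms(double lam, int y, int link,
                             double &ll, double &g, double &w) {
  if (lam > LAM_HI) lam = LAM_HI;
  if (lam < LAM_LO) lam = LAM_LO;
  if (link == 0) {
    double p = 1.0 / (1.0 + std::exp(-lam));
    ll = (y == 1) ? -std::log1p(std::exp(-lam)) : -std::log1p(std::exp(lam));
    g = (double)y - p;
    w = p * (1.0 - p);
    if (w < 1e-12) w = 1e-12;
  } else {
    double u = std::exp(lam);
    if (y == 1) {
      double f = -std::expm1(-u);           // 1 - exp(-u)
      if (f < 1e-300) f = 1e-300;
      double g1 = u * std::exp(-u) / f;
      ll = std::log(f);
      g = g1;
      w = g1 * g1 + g1 * (u - 1.0);
      if (w < 1e-12) w = 1e-12;
    } else {
      ll = -u;
      g = -u;
      w = u;
      if (w < 1e-12) w = 1e-12;
    }
  }
}

// evaluate unpenalized log-likelihood, score vector and weights
static double eval_all(const arma::mat &X, const arma::ivec &y,
                       const arma::vec &beta, int link,
                       arma::vec &score, arma::vec &wts, bool need_gw) {
  arma::vec lam = X * beta;
  const arma::uword n = lam.n_elem;
  double ll = 0.0;
  if (need_gw) { score.set_size(n); wts.set_size(n); }
  for (arma::uword t = 0; t < n; ++t) {
    double l, g, w;
    bin_terms(lam[t], y[t], link, l, g, w);
    ll += l;
    if (need_gw) { score[t] = g; wts[t] = w; }
  }
  return ll;
}

static double loglik_only(const arma::mat &X, const arma::ivec &y,
                          const arma::vec &beta, int link) {
  arma::vec s, w;
  return eval_all(X, y, beta, link, s, w, false);
}

// [[Rcpp::export]]
double cpp_loglik(const arma::mat &X, const arma::ivec &y,
                  const arma::vec &beta, int link) {
  return loglik_only(X, y, beta, link);
}

// Observed information X' W X of the unpenalized log-likelihood at beta.
// [[Rcpp::export]]
arma::mat cpp_info_matrix(const arma::mat &X, const arma::ivec &y,
                          const arma::vec &beta, int link) {
  arma::vec score, wts;
  eval_all(X, y, beta, link, score, wts, true);
  return X.t() * (X.each_col() % wts);
}

// Convolve spike trains with basis filters into the GLM design matrix.
// spikes: C_total x T (0/1), basis: K x M, ext: L x T (L may be 0).
// Rows correspond to bins t = M+1, ..., T (1-based); columns are
// [intercept | ext_1..L | (c=1,k=1..K) ... (c=C_total,k=1..K)].
// [[Rcpp::export]]
arma::mat cpp_design_matrix(const arma::imat &spikes, const arma::mat &basis,
                            const arma::mat &ext) {
  const int C = spikes.n_rows, T = spikes.n_cols;
  const int K = basis.n_rows, M = basis.n_cols;
  const int L = ext.n_rows;
  const int n = T - M;
  if (n < 1) stop("T must exceed the basis lag window M");
  arma::mat X(n, 1 + L + C * K, arma::fill::zeros);
  X.col(0).ones();
  for (int l = 0; l < L; ++l)
    for (int r = 0; r < n; ++r) X(r, 1 + l) = ext(l, M + r);
  for (int c = 0; c < C; ++c) {
    const int off = 1 + L + c * K;
    for (int t0 = 0; t0 < T; ++t0) {
      if (spikes(c, t0) == 0) continue;
      // spike at bin t0 (0-based) contributes at t = t0 + s, s = 1..M
      for (int s = 1; s <= M; ++s) {
        int r = t0 + s - M;  // row for bin index t0 + s
        if (r < 0 || r >= n) continue;
        for (int k = 0; k < K; ++k) X(r, off + k) += basis(k, s - 1);
      }
    }
  }
  return X;
}

// Newton maximization of ll - (eta/2) * sum(pen_j beta_j^2) with step halving.
// [[Rcpp::export]]
List cpp_newton_fit(const arma::mat &X, const arma::ivec &y, double eta,
                    const arma::vec &pen, int link, arma::vec beta,
                    double tol, int maxit, bool want_hessian) {
  const arma::uword p = X.n_cols;
  arma::vec score, wts;
  double ll = eval_all(X, y, beta, link, score, wts, true);
  double obj = ll - 0.5 * eta * arma::dot(pen, arma::square(beta));
  bool converged = false;
  int it = 0;
  arma::mat H;
  for (it = 0; it < maxit; ++it) {
    arma::vec grad = X.t() * score - eta * (pen % beta);
    double gmax = arma::abs(grad).max();
    if (gmax < 1e-7 * (1.0 + std::abs(obj))) { converged = true; break; }
    H = X.t() * (X.each_col() % wts);
    H.diag() += eta * pen + 1e-10;
    arma::vec delta;
    if (!arma::solve(delta, H, grad, arma::solve_opts::likely_sympd)) {
      H.diag() += 1e-6 * (arma::trace(H) / p + 1.0);
      delta = arma::solve(H, grad);
    }
    double step = 1.0, new_obj = -arma::datum::inf;
    arma::vec cand;
    for (int h = 0; h < 40; ++h) {
      cand = beta + step * delta;
      double cll = loglik_only(X, y, cand, link);
      new_obj = cll - 0.5 * eta * arma::dot(pen, arma::square(cand));
      if (new_obj >= obj - 1e-12) break;
      step *= 0.5;
    }
    double dobj = new_obj - obj;
    beta = cand;
    ll = eval_all(X, y, beta, link, score, wts, true);
    obj = ll - 0.5 * eta * arma::dot(pen, arma::square(beta));
    if (std::abs(dobj) < tol * (std::abs(obj) + 1.0)) {
      arma::vec grad2 = X.t() * score - eta * (pen % beta);
      if (arma::abs(grad2).max() < 1e-5 * (1.0 + std::abs(obj))) {
        converged = true; ++it; break;
      }
    }
  }
  List out = List::create(
      _["beta"] = beta, _["objective"] = obj, _["loglik"] = ll,
      _["converged"] = converged, _["iterations"] = it);
  if (want_hessian) {
    H = X.t() * (X.each_col() % wts);
    H.diag() += eta * pen;
    out["hessian"] = H;
  }
  return out;
}

// Refit with a frozen metric: preconditioned ascent using a fixed information
// matrix H (typically from the alternative fit with the dropped columns
// removed). Used for the many likelihood-ratio null refits; falls back to
// full Newton in R if it fails to converge.
// [[Rcpp::export]]
List cpp_refit_frozen(const arma::mat &X, const arma::ivec &y, double eta,
                      const arma::vec &pen, int link, arma::vec beta,
                      const arma::mat &H, double tol, int maxit) {
  arma::mat Hc;
  arma::mat Hj = H;
  if (!arma::chol(Hc, Hj)) {
    Hj.diag() += 1e-6 * (arma::trace(Hj) / Hj.n_rows + 1.0);
    arma::chol(Hc, Hj);
  }
  arma::vec score, wts;
  double ll = eval_all(X, y, beta, link, score, wts, true);
  double obj = ll - 0.5 * eta * arma::dot(pen, arma::square(beta));
  bool converged = false;
  int it;
  for (it = 0; it < maxit; ++it) {
    arma::vec grad = X.t() * score - eta * (pen % beta);
    if (arma::abs(grad).max() < 1e-7 * (1.0 + std::abs(obj))) {
      converged = true; break;
    }
    arma::vec delta = arma::solve(arma::trimatu(Hc),
                                  arma::solve(arma::trimatl(Hc.t()), grad));
    double step = 1.0, new_obj = -arma::datum::inf;
    arma::vec cand;
    for (int h = 0; h < 40; ++h) {
      cand = beta + step * delta;
      double cll = loglik_only(X, y, cand, link);
      new_obj = cll - 0.5 * eta * arma::dot(pen, arma::square(cand));
      if (new_obj >= obj - 1e-12) break;
      step *= 0.5;
    }
    double dobj = std::abs(new_obj - obj);
    beta = cand;
    ll = eval_all(X, y, beta, link, score, wts, true);
    obj = ll - 0.5 * eta * arma::dot(pen, arma::square(beta));
    if (dobj < tol * (std::abs(obj) + 1.0)) {
      arma::vec grad2 = X.t() * score - eta * (pen % beta);
      if (arma::abs(grad2).max() < 1e-5 * (1.0 + std::abs(obj))) {
        converged = true; ++it; break;
      }
    }
  }
  return List::create(_["beta"] = beta, _["objective"] = obj,
                      _["loglik"] = ll, _["converged"] = converged,
                      _["iterations"] = it);
}

static double penalty_value(const arma::vec &beta, const arma::ivec &groups,
                            int ngroups) {
  // group-lasso penalty: sum over groups of Euclidean norms; coordinates
  // with group id -1 are unpenalized. L1 is the special case of singleton
  // groups.
  arma::vec ss(ngroups, arma::fill::zeros);
  for (arma::uword j = 0; j < beta.n_elem; ++j)
    if (groups[j] >= 0) ss[groups[j]] += beta[j] * beta[j];
  return arma::accu(arma::sqrt(ss));
}

static void prox_group(arma::vec &beta, const arma::ivec &groups, int ngroups,
                       double thr) {
  arma::vec ss(ngroups, arma::fill::zeros);
  for (arma::uword j = 0; j < beta.n_elem; ++j)
    if (groups[j] >= 0) ss[groups[j]] += beta[j] * beta[j];
  arma::vec scale(ngroups);
  for (int g = 0; g < ngroups; ++g) {
    double nrm = std::sqrt(ss[g]);
    scale[g] = (nrm > thr) ? (1.0 - thr / nrm) : 0.0;
  }
  for (arma::uword j = 0; j < beta.n_elem; ++j)
    if (groups[j] >= 0) beta[j] *= scale[groups[j]];
}

// FISTA with backtracking and adaptive restart for max ll - eta * sum_g ||b_g||.
// groups: per-column group id (0-based), -1 for unpenalized columns.
// [[Rcpp::export]]
List cpp_fista_fit(const arma::mat &X, const arma::ivec &y, double eta,
                   const arma::ivec &groups, int link, arma::vec beta,
                   double tol, int maxit, double L0) {
  const int ngroups = groups.max() + 1;
  arma::vec score, wts;
  auto Fsmooth = [&](const arma::vec &b) { return -loglik_only(X, y, b, link); };
  auto Ftotal = [&](const arma::vec &b) {
    return Fsmooth(b) + eta * penalty_value(b, groups, ngroups);
  };
  arma::vec xk = beta, yk = beta;
  double tk = 1.0;
  double L = (L0 > 0) ? L0 : 1.0;
  double Fx = Ftotal(xk);
  bool converged = false;
  int it;
  for (it = 0; it < maxit; ++it) {
    double lly = eval_all(X, y, yk, link, score, wts, true);
    double fy = -lly;
    arma::vec grad = -(X.t() * score);
    arma::vec z;
    double fz;
    for (int bt = 0; bt < 60; ++bt) {
      z = yk - grad / L;
      prox_group(z, groups, ngroups, eta / L);
      fz = Fsmooth(z);
      arma::vec dz = z - yk;
      double quad = fy + arma::dot(grad, dz) + 0.5 * L * arma::dot(dz, dz);
      if (fz <= quad + 1e-12 * (std::abs(quad) + 1.0)) break;
      L *= 2.0;
    }
    double Fz = fz + eta * penalty_value(z, groups, ngroups);
    double tk1 = 0.5 * (1.0 + std::sqrt(1.0 + 4.0 * tk * tk));
    if (Fz > Fx) {  // adaptive restart
      yk = xk;
      tk = 1.0;
      if (std::abs(Fz - Fx) < tol * (std::abs(Fx) + 1.0)) { converged = true; break; }
      continue;
    }
    arma::vec xk1 = z;
    yk = xk1 + ((tk - 1.0) / tk1) * (xk1 - xk);
    double dF = Fx - Fz;
    xk = xk1;
    Fx = Fz;
    tk = tk1;
    if (dF < tol * (std::abs(Fx) + 1.0) && it > 5) { converged = true; ++it; break; }
    L = std::max(L / 1.5, 1e-3);
  }
  double ll = loglik_only(X, y, xk, link);
  return List::create(
      _["beta"] = xk, _["objective"] = -Fx, _["loglik"] = ll,
      _["converged"] = converged, _["iterations"] = it);
}

// Sequential simulation of a recurrent Bernoulli-GLM spiking network.
// adjacency(c, i): signed weight of connection c -> i, scaling the unit-peak
// kernel. priv_p: per-neuron private Poisson-input probability per bin;
// shared: L x T real signals with couplings shared_coef (C x L).
// Uses R's RNG so results are reproducible via set.seed().
// [[Rcpp::export]]
IntegerMatrix cpp_simulate(const arma::vec &baselines, const arma::mat &adjacency,
                           const arma::vec &kernel, const arma::vec &priv_p,
                           double priv_coef, const arma::mat &shared,
                           const arma::mat &shared_coef, int link, int T) {
  const int C = baselines.n_elem;
  const int Mg = kernel.n_elem;
  const int L = shared.n_rows;
  IntegerMatrix spikes(C, T);
  arma::mat drive(C, T, arma::fill::zeros);
  // presynaptic targets for each neuron
  std::vector<std::vector<int>> targets(C);
  for (int c = 0; c < C; ++c)
    for (int i = 0; i < C; ++i)
      if (adjacency(c, i) != 0.0) targets[c].push_back(i);
  for (int t = 0; t < T; ++t) {
    for (int i = 0; i < C; ++i) {
      double lam = baselines[i] + drive(i, t);
      if (priv_p[i] > 0.0 && unif_rand() < priv_p[i]) lam += priv_coef;
      for (int l = 0; l < L; ++l) lam += shared_coef(i, l) * shared(l, t);
      if (lam > LAM_HI) lam = LAM_HI;
      if (lam < LAM_LO) lam = LAM_LO;
      double p = (link == 0) ? 1.0 / (1.0 + std::exp(-lam))
                             : -std::expm1(-std::exp(lam));
      if (unif_rand() < p) {
        spikes(i, t) = 1;
        for (int j : targets[i]) {
          double w = adjacency(i, j);
          for (int s = 1; s <= Mg; ++s) {
            if (t + s >= T) break;
            drive(j, t + s) += w * kernel[s - 1];
          }
        }
      }
    }
  }
  return spikes;
}
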