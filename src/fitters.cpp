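// Iteratively reweighted least-squares engines for the logistic likelihood
// and its Jeffreys-penalized (Firth) variant, plus a per-variant test
// battery used by the replicate-based evaluation driver.  Kept in compiled
// code because the evaluation loops run hundreds of thousands of fits.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double WEIGHT_FLOOR = 1e-12;

// log(1 + exp(x)) without overflow
static inline double log1p_exp(double x) {
  if (x > 35.0) return x + std::exp(-x);
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

static double binom_loglik(const vec& y, const vec& eta) {
  double ll = 0.0;
  for (uword i = 0; i < y.n_elem; ++i)
    ll += y[i] * eta[i] - log1p_exp(eta[i]);
  return ll;
}

// 0.5 * log det(X'WX) via Cholesky; returns false if not PD
static bool half_logdet(const mat& XtWX, double& out) {
  mat R;
  if (!chol(R, symmatu(XtWX))) return false;
  out = accu(log(R.diag()));
  return true;
}

struct FitResult {
  vec beta;
  vec fitted;
  double loglik;
  double penloglik;   // NaN for plain MLE
  bool converged;
  bool separated;
  bool ok;            // false on numerical failure (e.g. rank deficiency)
  int iter;
};

static bool is_separated(const vec& beta, const vec& pi) {
  if (abs(beta).max() > 15.0) return true;
  for (uword i = 0; i < pi.n_elem; ++i)
    if (pi[i] < 1e-10 || pi[i] > 1.0 - 1e-10) return true;
  return false;
}

// Standard logistic MLE by Newton/IRLS with step halving.
// Convergence on relative log-likelihood change (glm-style) or score norm.
static FitResult mle_fit(const mat& X, const vec& y, int maxit, double tol,
                         const vec* init) {
  const uword p = X.n_cols;
  FitResult res;
  res.beta = init ? *init : zeros<vec>(p);
  res.ok = true; res.converged = false; res.separated = false;
  res.penloglik = datum::nan;

  vec eta = X * res.beta;
  vec pi = 1.0 / (1.0 + exp(-eta));
  double ll = binom_loglik(y, eta);
  int it = 0;
  for (; it < maxit; ++it) {
    vec w = clamp(pi % (1.0 - pi), WEIGHT_FLOOR, datum::inf);
    mat Xw = X.each_col() % w;
    mat XtWX = X.t() * Xw;
    vec U = X.t() * (y - pi);
    vec delta;
    if (!solve(delta, symmatu(XtWX), U, solve_opts::no_approx)) {
      res.ok = false; break;
    }
    double step = 1.0;
    vec beta_new; double ll_new = 0.0;
    bool improved = false;
    for (int h = 0; h < 30; ++h) {
      beta_new = res.beta + step * delta;
      ll_new = binom_loglik(y, X * beta_new);
      if (std::isfinite(ll_new) && ll_new >= ll - 1e-12) { improved = true; break; }
      step *= 0.5;
    }
    if (!improved) { res.converged = true; break; }  // cannot improve: at optimum
    double change = std::fabs(ll_new - ll) / (std::fabs(ll_new) + 0.1);
    res.beta = beta_new;
    eta = X * res.beta;
    pi = 1.0 / (1.0 + exp(-eta));
    ll = ll_new;
    if (change < tol || norm(U, "inf") < 1e-8) { res.converged = true; break; }
  }
  res.iter = it;
  res.loglik = ll;
  res.fitted = pi;
  if (res.ok) {
    res.separated = is_separated(res.beta, pi);
    if (res.separated) res.converged = false;
  }
  return res;
}

// Firth-penalized fit; coefficients whose indices appear in `fixed` are held
// at their initial values, the rest maximize the penalized likelihood of the
// FULL design (profile convention: the Jeffreys penalty always uses the full
// information matrix).
static FitResult firth_fit(const mat& X, const vec& y, const uvec& free_idx,
                           const vec& beta_init, int maxit,
                           double score_tol, double step_tol) {
  FitResult res;
  res.beta = beta_init;
  res.ok = true; res.converged = false; res.separated = false;
  const uword nf = free_idx.n_elem;

  vec eta = X * res.beta;
  vec pi = 1.0 / (1.0 + exp(-eta));
  double penll = -datum::inf;
  int it = 0;
  for (; it < maxit; ++it) {
    vec w = clamp(pi % (1.0 - pi), WEIGHT_FLOOR, datum::inf);
    mat XtWX = X.t() * (X.each_col() % w);
    mat R;
    if (!chol(R, symmatu(XtWX))) { res.ok = false; break; }
    double hld = accu(log(R.diag()));
    penll = binom_loglik(y, eta) + hld;
    // leverages of the W-weighted design: h_i = w_i * x_i' (X'WX)^{-1} x_i
    mat M = solve(trimatl(R.t()), X.t());     // p x n
    vec h = w % sum(square(M), 0).t();
    vec Ustar = X.t() * ((y - pi) + h % (0.5 - pi));
    vec Uf = Ustar(free_idx);
    if (norm(Uf, "inf") < score_tol) { res.converged = true; break; }
    mat If = XtWX(free_idx, free_idx);
    vec delta;
    if (!solve(delta, symmatu(If), Uf, solve_opts::no_approx)) {
      res.ok = false; break;
    }
    double step = 1.0;
    vec beta_new = res.beta;
    bool improved = false;
    double penll_new = penll;
    for (int hh = 0; hh < 30; ++hh) {
      beta_new = res.beta;
      for (uword k = 0; k < nf; ++k) beta_new[free_idx[k]] += step * delta[k];
      vec eta_new = X * beta_new;
      vec pi_new = 1.0 / (1.0 + exp(-eta_new));
      vec w_new = clamp(pi_new % (1.0 - pi_new), WEIGHT_FLOOR, datum::inf);
      double hld_new;
      if (half_logdet(X.t() * (X.each_col() % w_new), hld_new)) {
        penll_new = binom_loglik(y, eta_new) + hld_new;
        if (std::isfinite(penll_new) && penll_new >= penll - 1e-12) {
          improved = true; break;
        }
      }
      step *= 0.5;
    }
    if (!improved) { res.converged = true; break; }
    double maxchg = step * norm(delta, "inf");
    res.beta = beta_new;
    eta = X * res.beta;
    pi = 1.0 / (1.0 + exp(-eta));
    penll = penll_new;
    if (maxchg < step_tol) { res.converged = true; break; }
  }
  res.iter = it;
  res.fitted = pi;
  res.loglik = binom_loglik(y, eta);
  if (res.ok) {
    double hld;
    vec w = clamp(pi % (1.0 - pi), WEIGHT_FLOOR, datum::inf);
    if (half_logdet(X.t() * (X.each_col() % w), hld))
      res.penloglik = res.loglik + hld;
    else { res.ok = false; res.penloglik = datum::nan; }
  } else {
    res.penloglik = datum::nan;
  }
  return res;
}

static Rcpp::List wrap_fit(const FitResult& f) {
  return Rcpp::List::create(
    Rcpp::Named("beta") = f.beta,
    Rcpp::Named("fitted") = f.fitted,
    Rcpp::Named("loglik") = f.loglik,
    Rcpp::Named("penloglik") = f.penloglik,
    Rcpp::Named("converged") = f.converged,
    Rcpp::Named("separated") = f.separated,
    Rcpp::Named("ok") = f.ok,
    Rcpp::Named("iter") = f.iter);
}

// [[Rcpp::export(name = ".cpp_logistic_mle")]]
Rcpp::List cpp_logistic_mle(const arma::mat& X, const arma::vec& y,
                            int maxit = 100, double tol = 1e-10) {
  return wrap_fit(mle_fit(X, y, maxit, tol, nullptr));
}

// [[Rcpp::export(name = ".cpp_logistic_firth")]]
Rcpp::List cpp_logistic_firth(const arma::mat& X, const arma::vec& y,
                              const arma::uvec& free_idx,
                              const arma::vec& beta_init,
                              int maxit = 100, double score_tol = 1e-9,
                              double step_tol = 1e-10) {
  return wrap_fit(firth_fit(X, y, free_idx, beta_init, maxit,
                            score_tol, step_tol));
}

// Per-variant likelihood battery: for each genotype column g_j, fit the
// full-model MLE, the full-model Firth fit, and the Firth fit with the
// genotype coefficient held at zero (profile penalty).  Returns one row per
// variant: ll_full, mle_conv, mle_sep, lp_full, lp_null, firth_ok.
// [[Rcpp::export(name = ".cpp_sv_battery")]]
arma::mat cpp_sv_battery(const arma::mat& Xc, const arma::vec& y,
                         const arma::mat& G,
                         const arma::vec& firth_null_init,
                         const arma::vec& mle_null_init,
                         int maxit = 100) {
  const uword n = Xc.n_rows, p = Xc.n_cols, m = G.n_cols;
  mat out(m, 6); out.fill(datum::nan);
  mat Xj(n, p + 1);
  Xj.cols(0, p - 1) = Xc;
  uvec free_all = regspace<uvec>(0, p);        // all p+1 coefficients free
  uvec free_null = regspace<uvec>(0, p - 1);   // genotype coef fixed at 0
  vec mle_init(p + 1, fill::zeros);
  mle_init.head(p) = mle_null_init;
  for (uword j = 0; j < m; ++j) {
    Xj.col(p) = G.col(j);
    FitResult mle = mle_fit(Xj, y, 25, 1e-10, &mle_init);
    if (mle.ok) {
      out(j, 0) = mle.loglik;
      out(j, 1) = mle.converged ? 1.0 : 0.0;
      out(j, 2) = mle.separated ? 1.0 : 0.0;
    }
    vec init_full(p + 1, fill::zeros);
    init_full.head(p) = firth_null_init;
    // warm-start the full Firth fit from the MLE when it is finite
    if (mle.ok && !mle.separated && mle.converged) init_full = mle.beta;
    FitResult ff = firth_fit(Xj, y, free_all, init_full, maxit, 1e-7, 1e-10);
    vec init_con(p + 1, fill::zeros);
    init_con.head(p) = firth_null_init;
    // warm-start the constrained fit from the full fit's nuisance part
    if (ff.ok && ff.converged) {
      init_con = ff.beta; init_con[p] = 0.0;
    }
    FitResult f0 = firth_fit(Xj, y, free_null, init_con, maxit, 1e-7, 1e-10);
    if (ff.ok && f0.ok) {
      out(j, 3) = ff.penloglik;
      out(j, 4) = f0.penloglik;
      out(j, 5) = (ff.converged && f0.converged) ? 1.0 : 0.0;
    } else {
      out(j, 5) = 0.0;
    }
  }
  return out;
}
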