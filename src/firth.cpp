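// Firth-penalized logistic regression: Newton iterations on the
// modified score U*(beta) = X'(y - pi + h .* (0.5 - pi)), maximizing
// l(beta) + 0.5 * log det X'WX.  Called tens of thousands of times per
// stepwise search, hence compiled and organized so each iteration does
// one X'WX build, one Cholesky and one triangular solve.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct FirthState {
  vec pi, h, U;
  mat R;        // upper Cholesky factor of X'WX
  double pll;
  bool ok;
};

// Evaluate pi, hat diagonal, penalized log-likelihood and modified
// score at linear predictor eta.
static void eval_state(const mat& X, const vec& y, const vec& eta,
                       FirthState& st) {
  st.pi = 1.0 / (1.0 + exp(-eta));
  vec w = st.pi % (1.0 - st.pi);
  // weighted design: X'WX = Xw'Xw and h_i = || R^{-T} sqrt(w_i) x_i ||^2
  mat Xw = X.each_col() % sqrt(w);
  mat XtWX = Xw.t() * Xw;
  st.ok = chol(st.R, XtWX);
  if (!st.ok) { st.pll = -datum::inf; return; }
  double logdet = 2.0 * accu(log(st.R.diag()));
  mat T = solve(trimatl(st.R.t()), Xw.t());
  st.h = sum(square(T), 0).t();
  // stable softplus: log(1+e^eta) = max(eta,0) + log1p(e^{-|eta|})
  vec sp = clamp(eta, 0.0, datum::inf) + log1p(exp(-abs(eta)));
  st.pll = accu(y % eta - sp) + 0.5 * logdet;
  st.U = X.t() * (y - st.pi + st.h % (0.5 - st.pi));
}

// Newton loop with step-halving; returns false when the information
// matrix turns singular.  On success beta/st hold the optimum.
// Convergence: modified-score sup-norm < tol, or Newton step sup-norm
// below step_tol (the expected-information Hessian gives only linear
// convergence very close to the optimum, where the step collapses long
// before the score reaches a strict tolerance).
static bool fit_core(const mat& X, const vec& y, vec& beta, double tol,
                     int max_iter, FirthState& st, int& iters,
                     bool& converged) {
  const double step_tol = 1e-10;
  vec eta = X * beta;
  eval_state(X, y, eta, st);
  if (!st.ok) return false;
  iters = 0;
  converged = false;
  for (int iter = 1; iter <= max_iter; ++iter) {
    if (norm(st.U, "inf") < tol) { converged = true; return true; }
    iters = iter;
    vec step = solve(trimatu(st.R),
                     solve(trimatl(st.R.t()), st.U));
    if (norm(step, "inf") < step_tol) { converged = true; return true; }
    double pll_old = st.pll;
    // acceptance tolerance relative to the pll's own rounding noise
    const double acc_tol = 1e-10 * (std::abs(pll_old) + 1.0);
    vec beta_old = beta;
    for (int half = 0; half <= 30; ++half) {
      beta = beta_old + step;
      eta = X * beta;
      eval_state(X, y, eta, st);
      if (st.ok && st.pll >= pll_old - acc_tol) break;
      step *= 0.5;
      if (half == 30) {
        // step halved into numerical noise: we are at the optimum to
        // within the likelihood's floating-point resolution
        beta = beta_old;
        eval_state(X, y, X * beta, st);
        converged = st.ok;
        return st.ok;
      }
    }
    if (!st.ok) return false;
  }
  converged = norm(st.U, "inf") < tol;
  return true;
}

// [[Rcpp::export(name = ".firth_fit_cpp")]]
Rcpp::List firth_fit_cpp(const arma::mat& X, const arma::vec& y,
                         arma::vec beta, double tol, int max_iter) {
  FirthState st;
  int iters = 0;
  bool converged = false;
  if (!fit_core(X, y, beta, tol, max_iter, st, iters, converged))
    Rcpp::stop("singular Fisher information matrix");
  return Rcpp::List::create(
    Rcpp::Named("beta") = beta,
    Rcpp::Named("penalized_loglik") = st.pll,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("iterations") = iters,
    Rcpp::Named("hat_diag") = st.h,
    Rcpp::Named("fitted") = st.pi);
}

// Evaluate, for every column z of Z, the Firth fit of [Xbase, z].
// All candidate models share the same size, so a criterion comparison
// reduces to a penalized-log-likelihood threshold: with
// first_improving = true the scan stops at the first candidate whose
// pll exceeds pll_threshold (the directed-forward contract); otherwise
// all candidates are fitted (the exchange step picks the best in R).
// Candidates whose information matrix is singular get pll = -Inf.
// [[Rcpp::export(name = ".firth_batch_cpp")]]
Rcpp::List firth_batch_cpp(const arma::mat& Xbase, const arma::vec& y,
                           const arma::mat& Z, const arma::vec& beta_init,
                           double tol, int max_iter,
                           double pll_threshold, bool first_improving) {
  const uword q = Z.n_cols;
  const uword k = Xbase.n_cols;
  mat X(Xbase.n_rows, k + 1);
  X.head_cols(k) = Xbase;
  vec plls(q); plls.fill(datum::nan);
  int chosen = 0;
  FirthState st;

  // All candidates start from (beta_init, 0), so they share the same
  // linear predictor, weights and base-block factorization; the first
  // Newton step per candidate then costs O(nk) (rank-1 border of the
  // Cholesky factor) instead of O(nk^2).
  vec eta0 = Xbase * beta_init;
  vec pi0 = 1.0 / (1.0 + exp(-eta0));
  vec w0 = pi0 % (1.0 - pi0);
  vec sw0 = sqrt(w0);
  mat Xw = Xbase.each_col() % sw0;
  mat RA;
  bool base_ok = chol(RA, Xw.t() * Xw);
  mat Tb;                               // k x n: RA^{-T} Xw'
  vec hbase(Xbase.n_rows, fill::zeros);
  if (base_ok && k > 0) {
    Tb = solve(trimatl(RA.t()), Xw.t());
    hbase = sum(square(Tb), 0).t();
  }

  for (uword j = 0; j < q; ++j) {
    X.col(k) = Z.col(j);
    vec beta(k + 1);
    beta.head(k) = beta_init;
    beta(k) = 0.0;
    if (base_ok) {
      // bordered Cholesky of the augmented information matrix
      vec zw = Z.col(j) % sw0;
      double c = dot(zw, zw);
      vec u(k), tz(Xbase.n_rows);
      double d2;
      if (k > 0) {
        u = solve(trimatl(RA.t()), Xw.t() * zw);
        tz = zw - Tb.t() * u;
        d2 = c - dot(u, u);
      } else {
        tz = zw;
        d2 = c;
      }
      if (d2 <= 1e-10 * (c + 1e-300)) { plls(j) = -datum::inf; continue; }
      double d = std::sqrt(d2);
      vec haug = hbase + square(tz) / d2;
      vec r = y - pi0 + haug % (0.5 - pi0);
      vec U(k + 1);
      if (k > 0) U.head(k) = Xbase.t() * r;
      U(k) = dot(Z.col(j), r);
      // solve bordered system R'R step = U with R = [[RA, u],[0, d]]
      vec s(k + 1);
      if (k > 0) {
        vec t1 = solve(trimatl(RA.t()), U.head(k));
        double t2 = (U(k) - dot(u, t1)) / d;
        s(k) = t2 / d;
        s.head(k) = solve(trimatu(RA), t1 - u * s(k));
      } else {
        s(0) = U(0) / d2;
      }
      beta += s;
    }
    int iters = 0;
    bool conv = false;
    if (!fit_core(X, y, beta, tol, max_iter, st, iters, conv)) {
      // the accelerated start may (rarely) overshoot into a singular
      // region: retry once from the plain warm start
      beta.head(k) = beta_init;
      beta(k) = 0.0;
      if (!fit_core(X, y, beta, tol, max_iter, st, iters, conv)) {
        plls(j) = -datum::inf;
        continue;
      }
    }
    plls(j) = st.pll;
    if (first_improving && st.pll > pll_threshold) { chosen = j + 1; break; }
  }
  return Rcpp::List::create(Rcpp::Named("pll") = plls,
                            Rcpp::Named("chosen") = chosen);
}

// Penalized log-likelihood at a fixed beta (no fitting).
// [[Rcpp::export(name = ".firth_pll_cpp")]]
double firth_pll_cpp(const arma::mat& X, const arma::vec& y,
                     const arma::vec& beta) {
  FirthState st;
  eval_state(X, y, X * beta, st);
  if (!st.ok) Rcpp::stop("singular Fisher information matrix");
  return st.pll;
}
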