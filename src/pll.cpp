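#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Mean vector and temporal covariance matrix of the two-timescale model on a
// set of schedule frames, plus the Gaussian pseudo log-likelihood
//   -1/2 [ (y - mu)' Sigma^-1 (y - mu) + log det Sigma ].
// noise_var adds the residual background variance of a corrected trace
// (known from the region calibration) to the diagonal. Kept in compiled
// form because the numerical maximization evaluates it thousands of times
// per trace; the R-level covariance_matrix() is the reference
// implementation it is tested against.

// (T^d)[bright, bright] for d = 0..maxf-1
static void bright_return(const mat& T, int maxf, vec& h) {
  const int ns = T.n_rows;
  h.set_size(maxf);
  std::vector<double> w(ns, 0.0), tmp(ns);
  w[0] = 1.0;
  h(0) = 1.0;
  const double* Tp = T.memptr();
  for (int t = 1; t < maxf; ++t) {
    for (int j = 0; j < ns; ++j) {
      double s = 0.0;
      const double* col = Tp + j * ns;
      for (int i = 0; i < ns; ++i) s += w[i] * col[i];
      tmp[j] = s;
    }
    w.assign(tmp.begin(), tmp.end());
    h(t) = w[0];
  }
}

static void occupancy(const mat& T, double nu, int dark_start, int maxf,
                      vec& p) {
  const int ns = T.n_rows;
  p.set_size(maxf);
  std::vector<double> v(ns, 0.0), tmp(ns);
  v[0] = nu;
  v[dark_start - 1] += 1.0 - nu;
  p(0) = v[0];
  const double* Tp = T.memptr();
  for (int t = 1; t < maxf; ++t) {
    for (int j = 0; j < ns; ++j) {
      double s = 0.0;
      const double* col = Tp + j * ns;
      for (int i = 0; i < ns; ++i) s += v[i] * col[i];
      tmp[j] = s;
    }
    v.assign(tmp.begin(), tmp.end());
    p(t) = v[0];
  }
}

static void build_moments(const vec& frames, const mat& T, double m,
                          double EY, double sige2, double f2, double nu,
                          int dark_start, double noise_var,
                          vec& mu, mat& S) {
  const int n = frames.n_elem;
  const int maxf = (int) frames.max();
  vec p, h;
  occupancy(T, nu, dark_start, maxf, p);
  bright_return(T, maxf, h);
  vec pf(n);
  for (int i = 0; i < n; ++i) pf(i) = p((int) frames(i) - 1);
  mu = m * EY * pf;
  S.set_size(n, n);
  const double mE2 = m * EY * EY;
  for (int i = 0; i < n; ++i) {
    S(i, i) = ((sige2 + 1.0) * EY + f2 - EY * pf(i)) * m * EY * pf(i) +
      noise_var;
    for (int j = i + 1; j < n; ++j) {
      int d = (int) (frames(j) - frames(i));
      double cov = mE2 * pf(i) * (h(d) - pf(j));
      S(i, j) = cov;
      S(j, i) = cov;
    }
  }
}

// [[Rcpp::export]]
Rcpp::List cpp_trace_moments(const arma::vec& frames, const arma::mat& T,
                             double m, double EY, double sige2, double f2,
                             double nu, int dark_start,
                             double noise_var = 0.0) {
  vec mu;
  mat S;
  build_moments(frames, T, m, EY, sige2, f2, nu, dark_start, noise_var,
                mu, S);
  return Rcpp::List::create(Rcpp::Named("mu") = mu,
                            Rcpp::Named("Sigma") = S);
}

// [[Rcpp::export]]
Rcpp::List cpp_pseudo_loglik(const arma::vec& y, const arma::vec& frames,
                             const arma::mat& T, double m, double EY,
                             double sige2, double f2, double nu,
                             int dark_start, double noise_var,
                             double jitter_rel, double jitter_max_rel) {
  vec mu;
  mat S;
  build_moments(frames, T, m, EY, sige2, f2, nu, dark_start, noise_var,
                mu, S);
  const int n = y.n_elem;
  double dscale = mean(S.diag());
  if (!(dscale > 0) || !S.is_finite()) {
    return Rcpp::List::create(Rcpp::Named("value") = NA_REAL,
                              Rcpp::Named("ok") = false,
                              Rcpp::Named("jitter") = NA_REAL,
                              Rcpp::Named("diag_mean") = dscale);
  }
  // stabilizing jitter is always applied, then escalated tenfold on failure
  mat R;
  bool ok = false;
  double jit = 0.0;
  double added = 0.0;
  for (double rel = jitter_rel; rel <= jitter_max_rel * 1.0000001;
       rel *= 10.0) {
    jit = rel * dscale;
    S.diag() += jit - added;  // accumulate in place, no full-matrix copy
    added = jit;
    ok = chol(R, S, "upper");
    if (ok) break;
  }
  if (!ok) {
    return Rcpp::List::create(Rcpp::Named("value") = NA_REAL,
                              Rcpp::Named("ok") = false,
                              Rcpp::Named("jitter") = jit,
                              Rcpp::Named("diag_mean") = dscale);
  }
  vec z = solve(trimatl(R.t()), y - mu,
                solve_opts::fast + solve_opts::no_approx);
  double quad = dot(z, z);
  double logdet = 2.0 * sum(log(R.diag()));
  double val = -0.5 * (quad + logdet);
  if (!std::isfinite(val)) {
    return Rcpp::List::create(Rcpp::Named("value") = NA_REAL,
                              Rcpp::Named("ok") = false,
                              Rcpp::Named("jitter") = jit,
                              Rcpp::Named("diag_mean") = dscale);
  }
  return Rcpp::List::create(Rcpp::Named("value") = val,
                            Rcpp::Named("ok") = true,
                            Rcpp::Named("jitter") = jit,
                            Rcpp::Named("diag_mean") = dscale);
}
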