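// Gibbs sampler core for the longitudinal/outcome joint model.
//
// All randomness flows through R's RNG (R::norm_rand etc.), so set.seed()
// at the R level makes every entry point bit-reproducible. The per-block
// functions exported here are the same internals the main loop calls;
// tests validate them against quadrature oracles.
//
// Small fixed-size linear algebra (p ~ 9) uses hand-rolled Cholesky /
// triangular solves to avoid per-call LAPACK overhead inside the
// per-subject loops.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// ---- small numeric helpers -------------------------------------------------

static arma::mat sympd_inv(const arma::mat& A, const char* block) {
  arma::mat out;
  if (!arma::inv_sympd(out, A)) {
    arma::mat Aj = A + arma::eye(A.n_rows, A.n_rows) *
      (1e-10 * (arma::trace(A) / A.n_rows + 1.0));
    if (!arma::inv_sympd(out, Aj))
      stop("singular matrix in block '%s'", block);
  }
  return out;
}

// in-place lower Cholesky; returns false on failure
static bool chol_small_inplace(arma::mat& A) {
  const int p = A.n_rows;
  for (int j = 0; j < p; ++j) {
    double d = A(j, j);
    for (int k = 0; k < j; ++k) d -= A(j, k) * A(j, k);
    if (d <= 0.0) return false;
    d = std::sqrt(d);
    A(j, j) = d;
    for (int i = j + 1; i < p; ++i) {
      double s = A(i, j);
      for (int k = 0; k < j; ++k) s -= A(i, k) * A(j, k);
      A(i, j) = s / d;
    }
  }
  return true;
}

static void chol_small(arma::mat& A, const char* block) {
  if (!chol_small_inplace(A)) {
    double tr = 0.0;
    for (arma::uword i = 0; i < A.n_rows; ++i) tr += A(i, i);
    A.diag() += 1e-10 * (tr / A.n_rows + 1.0);
    if (!chol_small_inplace(A))
      stop("Cholesky failure in block '%s'", block);
  }
}

// solve L y = b, then L' x = y (uses lower triangle of L only)
static void chol_solve_inplace(const arma::mat& L, arma::vec& b) {
  const int p = L.n_rows;
  for (int i = 0; i < p; ++i) {
    double s = b(i);
    for (int k = 0; k < i; ++k) s -= L(i, k) * b(k);
    b(i) = s / L(i, i);
  }
  for (int i = p - 1; i >= 0; --i) {
    double s = b(i);
    for (int k = i + 1; k < p; ++k) s -= L(k, i) * b(k);
    b(i) = s / L(i, i);
  }
}

// x = mean + L^{-T} z gives x ~ N(mean, (L L')^{-1})
static void mvn_prec_draw_inplace(const arma::vec& mean, const arma::mat& L,
                                  arma::vec& out) {
  const int p = L.n_rows;
  for (int i = 0; i < p; ++i) out(i) = R::norm_rand();
  for (int i = p - 1; i >= 0; --i) {
    double s = out(i);
    for (int k = i + 1; k < p; ++k) s -= L(k, i) * out(k);
    out(i) = s / L(i, i);
  }
  out += mean;
}

static arma::mat chol_lower(const arma::mat& A, const char* block) {
  arma::mat L = A;
  chol_small(L, block);
  for (arma::uword j = 1; j < L.n_cols; ++j)
    for (arma::uword i = 0; i < j; ++i) L(i, j) = 0.0;
  return L;
}

static double rinvgamma(double shape, double rate) {
  return 1.0 / R::rgamma(shape, 1.0 / rate);
}

// Bartlett decomposition; scale given by its lower Cholesky factor
static arma::mat rwishart_chol(double df, const arma::mat& Lscale) {
  int p = Lscale.n_rows;
  arma::mat A(p, p, arma::fill::zeros);
  for (int i = 0; i < p; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  arma::mat LA = Lscale * A;
  return LA * LA.t();
}

static arma::mat rinvwishart(double df, const arma::mat& scale,
                             const char* block) {
  arma::mat W = rwishart_chol(df, chol_lower(sympd_inv(scale, block), block));
  return sympd_inv(W, block);
}

static arma::vec vech_lower(const arma::mat& A) {
  int p = A.n_rows;
  arma::vec v(p * (p + 1) / 2);
  int k = 0;
  for (int j = 0; j < p; ++j)
    for (int i = j; i < p; ++i) v(k++) = A(i, j);
  return v;
}

// ---- random-effect (b_i) full conditional ----------------------------------

static void cond_b_impl(const arma::mat& G, const arma::vec& h, double lnsig2,
                        const arma::mat& Sinv, const arma::vec& Sinv_beta,
                        const arma::vec& theta_b, double ry, double sigma2y,
                        arma::mat& prec, arma::vec& mean) {
  const int p = G.n_rows;
  const double w = std::exp(-lnsig2);
  const double iy = 1.0 / sigma2y;
  for (int j = 0; j < p; ++j)
    for (int i = j; i < p; ++i)
      prec(i, j) = w * G(i, j) + Sinv(i, j) + theta_b(i) * theta_b(j) * iy;
  mean = h * w + Sinv_beta + theta_b * (ry * iy);
}

// [[Rcpp::export]]
List gwg_cond_b(const arma::mat& G, const arma::vec& h, double lnsig2,
                const arma::mat& Sigma, const arma::vec& beta,
                const arma::vec& theta_b, double ry, double sigma2y) {
  const int p = G.n_rows;
  arma::mat Sinv = sympd_inv(Sigma, "b conditional");
  arma::mat prec(p, p); arma::vec mean(p);
  cond_b_impl(G, h, lnsig2, Sinv, Sinv * beta, theta_b, ry, sigma2y,
              prec, mean);
  arma::mat L = prec;
  chol_small(L, "b conditional");
  chol_solve_inplace(L, mean);
  prec = arma::symmatl(prec);
  return List::create(_["mean"] = mean,
                      _["cov"] = sympd_inv(prec, "b conditional"));
}

// [[Rcpp::export]]
arma::mat gwg_draw_b_rep(const arma::mat& G, const arma::vec& h, double lnsig2,
                         const arma::mat& Sigma, const arma::vec& beta,
                         const arma::vec& theta_b, double ry, double sigma2y,
                         int ndraw) {
  const int p = G.n_rows;
  arma::mat Sinv = sympd_inv(Sigma, "b conditional");
  arma::mat prec(p, p); arma::vec mean(p);
  cond_b_impl(G, h, lnsig2, Sinv, Sinv * beta, theta_b, ry, sigma2y,
              prec, mean);
  arma::mat L = prec;
  chol_small(L, "b conditional");
  chol_solve_inplace(L, mean);
  arma::mat out(ndraw, p);
  arma::vec x(p);
  for (int s = 0; s < ndraw; ++s) {
    mvn_prec_draw_inplace(mean, L, x);
    out.row(s) = x.t();
  }
  return out;
}

// ---- ln sigma_i^2 full conditional: grid inverse-CDF -----------------------
//
// unnormalized log conditional of lambda = ln sigma_i^2:
//   -n_i/2 * lambda - SSR_i/2 * exp(-lambda)
//   - (lambda - mu)^2 / (2 tau^2)
//   - (y - ay - theta_v * lambda)^2 / (2 sigma^2)
// which is strictly concave in lambda, so the mode is found by Newton.

static inline double lnsig2_logf(double lam, double n_i, double ssr,
                                 double mu, double tau2, double theta_v,
                                 double ay, double y, double sigma2y) {
  double ry = y - ay - theta_v * lam;
  return -0.5 * n_i * lam - 0.5 * ssr * std::exp(-lam)
       - 0.5 * (lam - mu) * (lam - mu) / tau2
       - 0.5 * ry * ry / sigma2y;
}

static double lnsig2_mode(double n_i, double ssr, double mu, double tau2,
                          double theta_v, double ay, double y, double sigma2y,
                          double lam0) {
  double lam = lam0;
  if (!std::isfinite(lam)) lam = (ssr > 0 && n_i > 0) ? std::log(ssr / n_i) : mu;
  for (int it = 0; it < 100; ++it) {
    double e = std::exp(-lam);
    double g = -0.5 * n_i + 0.5 * ssr * e - (lam - mu) / tau2
             + theta_v * (y - ay - theta_v * lam) / sigma2y;
    double hss = -0.5 * ssr * e - 1.0 / tau2 - theta_v * theta_v / sigma2y;
    double step = -g / hss;
    if (step > 2.0) step = 2.0;
    if (step < -2.0) step = -2.0;
    lam += step;
    if (std::fabs(step) < 1e-12) break;
  }
  return lam;
}

// grid offsets reused across subjects within one iteration
struct GridWork {
  arma::vec off, off2, eoff, w;
  double span = -1.0;
  int gsize = 0;
  void prepare(int g, double sp) {
    if (g == gsize && sp == span) return;
    gsize = g; span = sp;
    off = arma::linspace(-sp, sp, g);
    off2 = arma::square(off);
    eoff = arma::exp(-off);
    w.set_size(g);
  }
};

// fills gw.w with normalized masses over lambda = mode + gw.off;
// returns the mode. Written so the only transcendental per grid point is
// the final exp.
static double sigma_grid_weights(double n_i, double ssr, double mu,
                                 double tau2, double theta_v, double ay,
                                 double y, double sigma2y, double lam_init,
                                 GridWork& gw) {
  double mode = lnsig2_mode(n_i, ssr, mu, tau2, theta_v, ay, y, sigma2y,
                            lam_init);
  if (!std::isfinite(mode)) mode = mu; // recenter fallback
  const int g = gw.gsize;
  // logf(mode + off) = const + c1*off + c2*off^2 - B*exp(-off)
  const double c2 = -0.5 / tau2 - 0.5 * theta_v * theta_v / sigma2y;
  const double c1 = -0.5 * n_i + (mu - mode) / tau2
    + theta_v * (y - ay - theta_v * mode) / sigma2y;
  const double B = 0.5 * ssr * std::exp(-mode);
  double mx = -std::numeric_limits<double>::infinity();
  for (int j = 0; j < g; ++j) {
    double s = c1 * gw.off(j) + c2 * gw.off2(j) - B * gw.eoff(j);
    gw.w(j) = s;
    if (s > mx) mx = s;
  }
  if (!std::isfinite(mx))
    stop("ln sigma_i^2 grid underflowed after recentering");
  double tot = 0.0;
  for (int j = 0; j < g; ++j) {
    double e = std::exp(gw.w(j) - mx);
    gw.w(j) = e;
    tot += e;
  }
  if (!(tot > 0.0) || !std::isfinite(tot))
    stop("ln sigma_i^2 grid underflowed after recentering");
  gw.w /= tot;
  return mode;
}

// inverse CDF with within-cell linear interpolation
static double sigma_grid_draw(const GridWork& gw, double mode) {
  double u = R::unif_rand();
  const int g = gw.gsize;
  const double dx = gw.off(1) - gw.off(0);
  double c = 0.0;
  for (int j = 0; j < g; ++j) {
    double cn = c + gw.w(j);
    if (u <= cn || j == g - 1) {
      double frac = (gw.w(j) > 0) ? (u - c) / gw.w(j) : 0.5;
      if (frac < 0) frac = 0;
      if (frac > 1) frac = 1;
      return mode + gw.off(j) + dx * (frac - 0.5);
    }
    c = cn;
  }
  return mode + gw.off(g - 1); // unreachable
}

static double grid_span(double tau2, double span_mult, double span_min) {
  return std::max(span_mult * std::sqrt(tau2), span_min);
}

// [[Rcpp::export]]
List gwg_sigma_grid(double n_i, double ssr, double mu, double tau2,
                    double theta_v, double ay, double y, double sigma2y,
                    int grid_size = 2048, double span_mult = 8.0,
                    double span_min = 10.0, double lam_init = NA_REAL) {
  GridWork gw;
  gw.prepare(grid_size, grid_span(tau2, span_mult, span_min));
  double mode = sigma_grid_weights(n_i, ssr, mu, tau2, theta_v, ay, y,
                                   sigma2y, lam_init, gw);
  return List::create(_["lambda"] = mode + gw.off, _["w"] = gw.w,
                      _["cdf"] = arma::cumsum(gw.w), _["mode"] = mode);
}

// [[Rcpp::export]]
arma::vec gwg_draw_lnsig2_rep(double n_i, double ssr, double mu, double tau2,
                              double theta_v, double ay, double y,
                              double sigma2y, int grid_size = 2048,
                              double span_mult = 8.0, double span_min = 10.0,
                              double lam_init = NA_REAL, int ndraw = 1) {
  GridWork gw;
  gw.prepare(grid_size, grid_span(tau2, span_mult, span_min));
  double mode = sigma_grid_weights(n_i, ssr, mu, tau2, theta_v, ay, y,
                                   sigma2y, lam_init, gw);
  arma::vec out(ndraw);
  for (int s = 0; s < ndraw; ++s) out(s) = sigma_grid_draw(gw, mode);
  return out;
}

// ---- beta and theta conditionals (conjugate Gaussian) ----------------------

// [[Rcpp::export]]
List gwg_cond_beta(const arma::mat& b, const arma::mat& Sigma,
                   double beta_var) {
  int n = b.n_cols, p = b.n_rows;
  arma::mat Sinv = sympd_inv(Sigma, "beta conditional");
  arma::mat prec = n * Sinv + arma::eye(p, p) / beta_var;
  arma::vec mean = arma::solve(prec, Sinv * arma::sum(b, 1),
                               arma::solve_opts::likely_sympd);
  return List::create(_["mean"] = mean,
                      _["cov"] = sympd_inv(prec, "beta conditional"));
}

// [[Rcpp::export]]
List gwg_cond_theta(const arma::mat& W, const arma::vec& Y, double sigma2,
                    double theta_var) {
  int d = W.n_cols;
  arma::mat prec = W.t() * W / sigma2 + arma::eye(d, d) / theta_var;
  arma::vec mean = arma::solve(prec, W.t() * Y / sigma2,
                               arma::solve_opts::likely_sympd);
  return List::create(_["mean"] = mean,
                      _["cov"] = sympd_inv(prec, "theta conditional"));
}

// [[Rcpp::export]]
List gwg_cond_mu(const arma::vec& lnsig2, double tau2, double mu_mean,
                 double mu_var) {
  int n = lnsig2.n_elem;
  double v = 1.0 / (n / tau2 + 1.0 / mu_var);
  double m = v * (arma::accu(lnsig2) / tau2 + mu_mean / mu_var);
  return List::create(_["mean"] = m, _["var"] = v);
}

// ---- Sigma block -----------------------------------------------------------

// log target for the Wishart-on-covariance mode (up to a constant):
// ((m - p - 1 - n)/2) log|Sigma| - tr(Lambda^{-1} Sigma)/2 - tr(Sigma^{-1} S)/2
static double sigma_logtarget(const arma::mat& Sigma, const arma::mat& S,
                              double n, double m, const arma::mat& Lambda_inv) {
  int p = Sigma.n_rows;
  double sign, ld;
  if (!arma::log_det(ld, sign, Sigma) || sign <= 0)
    return -std::numeric_limits<double>::infinity();
  arma::mat Sinv = sympd_inv(Sigma, "Sigma target");
  return 0.5 * (m - p - 1 - n) * ld
       - 0.5 * arma::trace(Lambda_inv * Sigma)
       - 0.5 * arma::trace(Sinv * S);
}

// One independence Metropolis step. The proposal IW(max(n - m, p + 2),
// S + ridge I) matches the inverse-Wishart-shaped part of the target
// exactly: |Sigma|^{(m-p-1-n)/2} exp(-tr(Sigma^{-1} S)/2) is the
// IW(n - m, S) kernel, so for n > m + p + 1 the log acceptance ratio
// collapses to the bounded difference
//   -tr(Lambda^{-1} (Sigma* - Sigma))/2 (+ ridge correction),
// giving near-certain acceptance whenever the Wishart prior factor is
// mild relative to the random-effect scatter, and graceful degradation --
// never a stuck chain -- when it is not.
static bool sigma_mh_step(arma::mat& Sigma, const arma::mat& S, double n,
                          double m, const arma::mat& Lambda_inv) {
  int p = Sigma.n_rows;
  double ridge = 1e-8 * (arma::trace(S) / p + 1.0);
  arma::mat Sq = S + ridge * arma::eye(p, p);
  double nu_q = std::max(n - m, p + 2.0);
  arma::mat prop = rinvwishart(nu_q, Sq, "Sigma proposal");
  double sign, ld_cur, ld_prop;
  arma::log_det(ld_cur, sign, Sigma);
  arma::log_det(ld_prop, sign, prop);
  // log proposal density up to constants
  double lq_cur = -0.5 * (nu_q + p + 1) * ld_cur
    - 0.5 * arma::trace(Sq * sympd_inv(Sigma, "Sigma proposal"));
  double lq_prop = -0.5 * (nu_q + p + 1) * ld_prop
    - 0.5 * arma::trace(Sq * sympd_inv(prop, "Sigma proposal"));
  double la = sigma_logtarget(prop, S, n, m, Lambda_inv)
            - sigma_logtarget(Sigma, S, n, m, Lambda_inv)
            + lq_cur - lq_prop;
  if (std::log(R::unif_rand()) < la) {
    Sigma = prop;
    return true;
  }
  return false;
}

// [[Rcpp::export]]
List gwg_sigma_mh_chain(const arma::mat& Sigma0, const arma::mat& S, double n,
                        double m, const arma::mat& Lambda, int iters) {
  arma::mat Sigma = Sigma0;
  arma::mat Lambda_inv = sympd_inv(Lambda, "Sigma prior");
  int p = Sigma.n_rows;
  arma::mat draws(iters, p * (p + 1) / 2);
  int acc = 0;
  for (int it = 0; it < iters; ++it) {
    if (sigma_mh_step(Sigma, S, n, m, Lambda_inv)) ++acc;
    draws.row(it) = vech_lower(Sigma).t();
  }
  return List::create(_["draws"] = draws, _["accept"] = (double)acc / iters,
                      _["last"] = Sigma);
}

// [[Rcpp::export]]
List gwg_sigma_conj_params(const arma::mat& S, double n, double m,
                           const arma::mat& Lambda) {
  return List::create(_["df"] = m + n, _["scale"] = Lambda + S);
}

// [[Rcpp::export]]
arma::mat gwg_draw_invwishart_rep(double df, const arma::mat& scale,
                                  int ndraw) {
  int p = scale.n_rows;
  arma::mat out(ndraw, p * (p + 1) / 2);
  for (int s = 0; s < ndraw; ++s)
    out.row(s) = vech_lower(rinvwishart(df, scale, "invwishart")).t();
  return out;
}

// ---- main Gibbs loop -------------------------------------------------------

// [[Rcpp::export]]
List gwg_gibbs_run(const List& data, const List& priors, const List& init,
                   const List& config) {
  const arma::cube G = as<arma::cube>(data["G"]);
  const arma::mat h = as<arma::mat>(data["h"]);
  const arma::vec xx = as<arma::vec>(data["xx"]);
  const arma::vec nobs = as<arma::vec>(data["nobs"]);
  const arma::mat Z = as<arma::mat>(data["Z"]);
  const arma::vec Y = as<arma::vec>(data["Y"]);

  const double theta_var = as<double>(priors["theta_var"]);
  const double beta_var = as<double>(priors["beta_var"]);
  const double s2_a = as<double>(priors["sigma2_shape"]);
  const double s2_b = as<double>(priors["sigma2_rate"]);
  const double t2_a = as<double>(priors["tau2_shape"]);
  const double t2_b = as<double>(priors["tau2_rate"]);
  const double mu_m = as<double>(priors["mu_mean"]);
  const double mu_v = as<double>(priors["mu_var"]);
  const double wish_m = as<double>(priors["wishart_df"]);
  const arma::mat Lambda = as<arma::mat>(priors["Lambda"]);
  const int sigma_mode = as<int>(priors["sigma_mode"]); // 0 Wishart MH, 1 conjugate IW

  arma::vec theta = as<arma::vec>(init["theta"]);
  double sigma2 = as<double>(init["sigma2"]);
  arma::vec beta = as<arma::vec>(init["beta"]);
  arma::mat Sigma = as<arma::mat>(init["Sigma"]);
  double mu = as<double>(init["mu"]);
  double tau2 = as<double>(init["tau2"]);
  arma::mat b = as<arma::mat>(init["b"]);
  arma::vec lnsig2 = as<arma::vec>(init["lnsig2"]);

  const int iters = as<int>(config["iterations"]);
  const int burn = as<int>(config["burnin"]);
  const int thin = as<int>(config["thin"]);
  const int gsize = as<int>(config["grid_size"]);
  const double span_mult = as<double>(config["span_mult"]);
  const double span_min = as<double>(config["span_min"]);
  arma::uvec save_b = as<arma::uvec>(config["save_b_idx"]); // 1-based
  if (save_b.n_elem > 0) save_b -= 1;

  const int n = Y.n_elem, p = b.n_rows, q = Z.n_cols;
  const int d = 1 + q + p + 1;
  if ((int)theta.n_elem != d) stop("theta has wrong length");
  const int M = (iters - burn) / thin;
  const int nsave = save_b.n_elem;

  arma::mat out_theta(M, d), out_beta(M, p), out_Sigma(M, p * (p + 1) / 2);
  arma::vec out_mu(M), out_tau2(M), out_sigma2(M);
  arma::mat out_b(M, p * nsave), out_lnsig2(M, nsave);
  arma::mat b_mean(p, n, arma::fill::zeros);
  arma::vec lnsig2_mean(n, arma::fill::zeros);

  const arma::mat Lambda_inv = sympd_inv(Lambda, "Sigma prior");
  arma::mat W(n, d);
  W.col(0).ones();
  if (q > 0) W.cols(1, q) = Z;

  int sigma_prop = 0, sigma_acc = 0;
  int kept = 0;
  GridWork gw;
  arma::mat prec(p, p), L(p, p);
  arma::vec mean(p), bi(p);

  for (int it = 0; it < iters; ++it) {
    if (it % 1000 == 0) checkUserInterrupt();
    arma::mat Sinv = sympd_inv(Sigma, "Sigma inverse");
    arma::vec Sinv_beta = Sinv * beta;
    const double theta0 = theta(0);
    arma::vec theta_b = theta.subvec(1 + q, q + p);
    const double theta_v = theta(d - 1);
    arma::vec zeta(n, arma::fill::zeros);
    if (q > 0) zeta = Z * theta.subvec(1, q);

    // b_i block
    for (int i = 0; i < n; ++i) {
      double ry = Y(i) - theta0 - zeta(i) - theta_v * lnsig2(i);
      cond_b_impl(G.slice(i), h.col(i), lnsig2(i), Sinv, Sinv_beta, theta_b,
                  ry, sigma2, prec, mean);
      L = prec;
      chol_small(L, "b draw");
      chol_solve_inplace(L, mean);
      mvn_prec_draw_inplace(mean, L, bi);
      b.col(i) = bi;
    }

    // ln sigma_i^2 block (grid inverse-CDF)
    gw.prepare(gsize, grid_span(tau2, span_mult, span_min));
    for (int i = 0; i < n; ++i) {
      bi = b.col(i);
      double ssr = xx(i) - 2.0 * arma::dot(bi, h.col(i))
                 + arma::dot(bi, G.slice(i) * bi);
      if (ssr < 0) ssr = 0;
      double ay = theta0 + zeta(i) + arma::dot(theta_b, bi);
      double mode = sigma_grid_weights(nobs(i), ssr, mu, tau2, theta_v, ay,
                                       Y(i), sigma2, lnsig2(i), gw);
      lnsig2(i) = sigma_grid_draw(gw, mode);
    }

    // beta
    {
      arma::mat bprec = n * Sinv + arma::eye(p, p) / beta_var;
      arma::vec bmean = Sinv * arma::sum(b, 1);
      L = bprec;
      chol_small(L, "beta draw");
      chol_solve_inplace(L, bmean);
      mvn_prec_draw_inplace(bmean, L, bi);
      beta = bi;
    }

    // Sigma
    {
      arma::mat D = b.each_col() - beta;
      arma::mat S = D * D.t();
      if (sigma_mode == 1) {
        Sigma = rinvwishart(wish_m + n, Lambda + S, "Sigma conjugate");
      } else {
        ++sigma_prop;
        if (sigma_mh_step(Sigma, S, n, wish_m, Lambda_inv)) ++sigma_acc;
      }
    }

    // mu, tau2
    {
      double v = 1.0 / (n / tau2 + 1.0 / mu_v);
      double m = v * (arma::accu(lnsig2) / tau2 + mu_m / mu_v);
      mu = m + std::sqrt(v) * R::norm_rand();
      double ss = arma::accu(arma::square(lnsig2 - mu));
      tau2 = rinvgamma(t2_a + 0.5 * n, t2_b + 0.5 * ss);
    }

    // theta, sigma2
    {
      W.cols(1 + q, q + p) = b.t();
      W.col(d - 1) = lnsig2;
      arma::mat tprec = W.t() * W / sigma2
        + arma::eye(d, d) / theta_var;
      arma::vec tmean = W.t() * Y / sigma2;
      arma::mat Lt = tprec;
      chol_small(Lt, "theta draw");
      chol_solve_inplace(Lt, tmean);
      arma::vec tdraw(d);
      mvn_prec_draw_inplace(tmean, Lt, tdraw);
      theta = tdraw;
      arma::vec res = Y - W * theta;
      sigma2 = rinvgamma(s2_a + 0.5 * n, s2_b + 0.5 * arma::dot(res, res));
    }

    // retain
    if (it >= burn && (it - burn + 1) % thin == 0 && kept < M) {
      out_theta.row(kept) = theta.t();
      out_beta.row(kept) = beta.t();
      out_Sigma.row(kept) = vech_lower(Sigma).t();
      out_mu(kept) = mu;
      out_tau2(kept) = tau2;
      out_sigma2(kept) = sigma2;
      for (int s = 0; s < nsave; ++s) {
        out_b.submat(kept, s * p, kept, (s + 1) * p - 1) =
          b.col(save_b(s)).t();
        out_lnsig2(kept, s) = lnsig2(save_b(s));
      }
      b_mean += b;
      lnsig2_mean += lnsig2;
      ++kept;
    }
  }
  if (kept > 0) {
    b_mean /= kept;
    lnsig2_mean /= kept;
  }
  return List::create(
    _["theta"] = out_theta, _["beta"] = out_beta, _["Sigma"] = out_Sigma,
    _["mu"] = out_mu, _["tau2"] = out_tau2, _["sigma2"] = out_sigma2,
    _["b"] = out_b, _["lnsig2"] = out_lnsig2,
    _["b_mean"] = b_mean, _["lnsig2_mean"] = lnsig2_mean,
    _["sigma_accept"] = sigma_prop > 0 ? (double)sigma_acc / sigma_prop
                                       : NA_REAL,
    _["kept"] = kept);
}
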