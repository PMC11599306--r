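#include <Rcpp.h>
using namespace Rcpp;

// Gibbs samplers for variance-component mixed models with a single fixed
// intercept and any number of scalar random-intercept terms.
//
// Conventions shared by both samplers:
//  * G is an n x T matrix of 0-based level indices (one column per random
//    term); nlev gives the number of levels of each term.
//  * Each random term t has a scalar inverse-Wishart prior with parameters
//    (V_t, nu_t), i.e. sigma2_t ~ Inv-Gamma(shape = nu_t/2, rate = nu_t*V_t/2).
//  * The intercept prior is Normal(mu0, v0).
//  * Draws are stored after burn-in at the given thinning interval.
// R's RNG is used throughout, so set.seed() on the R side gives exact
// reproducibility.

static inline double rinvgamma(double shape, double rate) {
  // R::rgamma is parameterised by shape and scale
  return 1.0 / R::rgamma(shape, 1.0 / rate);
}

// Draw every level of term t from its normal full conditional given the
// partial residual r (response minus all other model terms).
static void update_term(const NumericVector& r, const IntegerVector& g,
                        int k, double sig2_t, double sig2_e,
                        NumericVector& u) {
  std::vector<double> sum(k, 0.0);
  std::vector<int> cnt(k, 0);
  const int n = r.size();
  for (int i = 0; i < n; ++i) {
    sum[g[i]] += r[i];
    cnt[g[i]] += 1;
  }
  for (int j = 0; j < k; ++j) {
    double prec = cnt[j] / sig2_e + 1.0 / sig2_t;
    double mean = (sum[j] / sig2_e) / prec;
    u[j] = R::rnorm(mean, std::sqrt(1.0 / prec));
  }
}

// [[Rcpp::export]]
List gibbs_gaussian_cpp(NumericVector y, IntegerMatrix G, IntegerVector nlev,
                        double mu0, double v0,
                        NumericVector term_nu, NumericVector term_V,
                        double resid_nu, double resid_V,
                        int iters, int burnin, int thin,
                        LogicalVector fix_term, NumericVector fix_term_value,
                        bool fix_resid, double fix_resid_value) {
  const int n = y.size();
  const int T = nlev.size();
  const int nstore = (iters - burnin) / thin;

  double mu = mean(y);
  double sig2_e = fix_resid ? fix_resid_value : var(y) + 1e-8;
  std::vector<NumericVector> u(T);
  NumericVector sig2(T);
  for (int t = 0; t < T; ++t) {
    u[t] = NumericVector(nlev[t], 0.0);
    sig2[t] = fix_term[t] ? fix_term_value[t] : 1.0;
  }

  NumericVector mu_draws(nstore), resid_draws(nstore);
  NumericMatrix var_draws(nstore, T);
  std::vector<NumericMatrix> u_draws(T);
  for (int t = 0; t < T; ++t) u_draws[t] = NumericMatrix(nstore, nlev[t]);

  NumericVector fitted_re(n); // sum of random effects per row
  NumericVector r(n);
  int stored = 0;

  for (int it = 0; it < iters; ++it) {
    // running total of random effects
    std::fill(fitted_re.begin(), fitted_re.end(), 0.0);
    for (int t = 0; t < T; ++t) {
      IntegerMatrix::Column g = G(_, t);
      for (int i = 0; i < n; ++i) fitted_re[i] += u[t][g[i]];
    }

    // intercept
    {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += y[i] - fitted_re[i];
      double prec = n / sig2_e + 1.0 / v0;
      double mean_ = (s / sig2_e + mu0 / v0) / prec;
      mu = R::rnorm(mean_, std::sqrt(1.0 / prec));
    }

    // random terms
    for (int t = 0; t < T; ++t) {
      IntegerMatrix::Column g = G(_, t);
      for (int i = 0; i < n; ++i)
        r[i] = y[i] - mu - (fitted_re[i] - u[t][g[i]]);
      update_term(r, g, nlev[t], sig2[t], sig2_e, u[t]);
      std::fill(fitted_re.begin(), fitted_re.end(), 0.0);
      for (int s = 0; s < T; ++s) {
        IntegerMatrix::Column gs = G(_, s);
        for (int i = 0; i < n; ++i) fitted_re[i] += u[s][gs[i]];
      }
      if (!fix_term[t]) {
        double ss = 0.0;
        for (int j = 0; j < nlev[t]; ++j) ss += u[t][j] * u[t][j];
        sig2[t] = rinvgamma((term_nu[t] + nlev[t]) / 2.0,
                            (term_nu[t] * term_V[t] + ss) / 2.0);
      }
    }

    // residual
    if (!fix_resid) {
      double ss = 0.0;
      for (int i = 0; i < n; ++i) {
        double e = y[i] - mu - fitted_re[i];
        ss += e * e;
      }
      sig2_e = rinvgamma((resid_nu + n) / 2.0, (resid_nu * resid_V + ss) / 2.0);
    }

    if (it >= burnin && (it - burnin) % thin == 0 && stored < nstore) {
      mu_draws[stored] = mu;
      resid_draws[stored] = sig2_e;
      for (int t = 0; t < T; ++t) {
        var_draws(stored, t) = sig2[t];
        for (int j = 0; j < nlev[t]; ++j) u_draws[t](stored, j) = u[t][j];
      }
      ++stored;
    }
  }

  List ul(T);
  for (int t = 0; t < T; ++t) ul[t] = u_draws[t];
  return List::create(_["intercept"] = mu_draws, _["variances"] = var_draws,
                      _["residual"] = resid_draws, _["effects"] = ul);
}

static inline double bern_loglik(int y, double l) {
  // y*l - log(1 + exp(l)), numerically stable
  double log1pe = (l > 0) ? l + std::log1p(std::exp(-l)) : std::log1p(std::exp(l));
  return y * l - log1pe;
}

// [[Rcpp::export]]
List gibbs_binary_cpp(IntegerVector y, IntegerMatrix G, IntegerVector nlev,
                      double mu0, double v0,
                      NumericVector term_nu, NumericVector term_V,
                      double resid_var,
                      int iters, int burnin, int thin,
                      double prop_sd_init) {
  const int n = y.size();
  const int T = nlev.size();
  const int nstore = (iters - burnin) / thin;

  double pbar = 0.0;
  for (int i = 0; i < n; ++i) pbar += y[i];
  pbar = std::min(std::max(pbar / n, 1.0 / (n + 1.0)), n / (n + 1.0));
  double mu = std::log(pbar / (1.0 - pbar));
  std::vector<NumericVector> u(T);
  NumericVector sig2(T);
  for (int t = 0; t < T; ++t) {
    u[t] = NumericVector(nlev[t], 0.0);
    sig2[t] = 1.0;
  }
  // latent log-odds, one per individual; prior N(linear predictor, resid_var)
  double spread = std::min(1.0, std::sqrt(resid_var));
  NumericVector l(n);
  for (int i = 0; i < n; ++i) l[i] = mu + (y[i] == 1 ? spread : -spread);

  double prop_sd = prop_sd_init;
  long acc = 0, tries = 0;       // within current adaptation batch
  long acc_all = 0, tries_all = 0; // post burn-in

  NumericVector mu_draws(nstore), pred_draws(nstore);
  NumericMatrix var_draws(nstore, T);
  std::vector<NumericMatrix> u_draws(T);
  for (int t = 0; t < T; ++t) u_draws[t] = NumericMatrix(nstore, nlev[t]);

  NumericVector linpred(n), r(n);
  int stored = 0;

  for (int it = 0; it < iters; ++it) {
    // linear predictor
    for (int i = 0; i < n; ++i) linpred[i] = mu;
    for (int t = 0; t < T; ++t) {
      IntegerMatrix::Column g = G(_, t);
      for (int i = 0; i < n; ++i) linpred[i] += u[t][g[i]];
    }

    // Metropolis update of the latent variables
    for (int i = 0; i < n; ++i) {
      double lp = l[i] + R::rnorm(0.0, prop_sd);
      double d = bern_loglik(y[i], lp) - bern_loglik(y[i], l[i]);
      double e0 = l[i] - linpred[i], e1 = lp - linpred[i];
      d -= (e1 * e1 - e0 * e0) / (2.0 * resid_var);
      ++tries;
      if (d >= 0.0 || R::unif_rand() < std::exp(d)) {
        l[i] = lp;
        ++acc;
      }
    }
    if (it < burnin) {
      // adapt the proposal scale toward ~44% acceptance in batches
      if (tries >= 50L * n) {
        double rate = (double)acc / tries;
        prop_sd *= std::exp(rate - 0.44);
        acc = 0; tries = 0;
      }
    } else {
      acc_all += acc; tries_all += tries; acc = 0; tries = 0;
    }

    // intercept, with l as the Gaussian response
    {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += l[i] - (linpred[i] - mu);
      double prec = n / resid_var + 1.0 / v0;
      double mean_ = (s / resid_var + mu0 / v0) / prec;
      mu = R::rnorm(mean_, std::sqrt(1.0 / prec));
    }

    // random terms
    for (int t = 0; t < T; ++t) {
      // recompute linear predictor excluding term t
      for (int i = 0; i < n; ++i) r[i] = l[i] - mu;
      for (int s = 0; s < T; ++s) {
        if (s == t) continue;
        IntegerMatrix::Column gs = G(_, s);
        for (int i = 0; i < n; ++i) r[i] -= u[s][gs[i]];
      }
      IntegerMatrix::Column g = G(_, t);
      update_term(r, g, nlev[t], sig2[t], resid_var, u[t]);
      double ss = 0.0;
      for (int j = 0; j < nlev[t]; ++j) ss += u[t][j] * u[t][j];
      sig2[t] = rinvgamma((term_nu[t] + nlev[t]) / 2.0,
                          (term_nu[t] * term_V[t] + ss) / 2.0);
    }

    if (it >= burnin && (it - burnin) % thin == 0 && stored < nstore) {
      mu_draws[stored] = mu;
      for (int t = 0; t < T; ++t) {
        var_draws(stored, t) = sig2[t];
        for (int j = 0; j < nlev[t]; ++j) u_draws[t](stored, j) = u[t][j];
      }
      double p = 0.0;
      for (int i = 0; i < n; ++i) p += 1.0 / (1.0 + std::exp(-l[i]));
      pred_draws[stored] = p / n;
      ++stored;
    }
  }

  List ul(T);
  for (int t = 0; t < T; ++t) ul[t] = u_draws[t];
  double acc_rate = tries_all > 0 ? (double)acc_all / tries_all : NA_REAL;
  return List::create(_["intercept"] = mu_draws, _["variances"] = var_draws,
                      _["effects"] = ul, _["pred_prop"] = pred_draws,
                      _["acceptance"] = acc_rate, _["prop_sd"] = prop_sd);
}
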