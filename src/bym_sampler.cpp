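#include <Rcpp.h>
using namespace Rcpp;

// Metropolis-within-Gibbs sampler for the BYM Poisson log-linear model.
// Mirrors the R reference engine: univariate random-walk updates of
// alpha, beta_k, u_i, v_i (the latter against the CAR full conditional),
// recentring of v after each sweep with the mean absorbed into alpha,
// then conjugate gamma draws of the two precisions. Proposal scales adapt
// in windows of 50 sweeps during burn-in only.

// [[Rcpp::export]]
List bym_mcmc_cpp(NumericVector O, NumericVector E, NumericMatrix X,
                  List nb, int n_components,
                  int n_iter, int n_burnin, int thin,
                  double hyper_shape, double hyper_rate,
                  double alpha_sd, double beta_sd,
                  bool adapt, bool spatial, bool fix_tau,
                  double tau_u_fixed, double tau_v_fixed) {
  const int n = O.size();
  const int k = X.ncol();
  const int n_kept = n_iter / thin;

  std::vector< std::vector<int> > nbr(n);
  std::vector<int> free_ix;
  for (int i = 0; i < n; ++i) {
    IntegerVector v = nb[i];
    nbr[i] = std::vector<int>(v.begin(), v.end());
    if (spatial && nbr[i].size() > 0) free_ix.push_back(i);
  }
  const int n_free = free_ix.size();

  // active units per covariate (beta_k only touches units with x_ik != 0)
  std::vector< std::vector<int> > active(k);
  for (int j = 0; j < k; ++j)
    for (int i = 0; i < n; ++i)
      if (X(i, j) != 0.0) active[j].push_back(i);

  double alpha = std::log((sum(O) + 0.5) / sum(E));
  std::vector<double> u(n, 0.0), v(n, 0.0), beta(k, 0.0);
  double tau_u = fix_tau ? tau_u_fixed : 10.0;
  double tau_v = fix_tau ? tau_v_fixed : 10.0;

  std::vector<double> eta(n);
  for (int i = 0; i < n; ++i) eta[i] = alpha;

  double sc_alpha = 0.1;
  std::vector<double> sc_beta(k, 0.1), sc_u(n, 0.3), sc_v(n, 0.3);

  double acc_alpha = 0.0;
  std::vector<double> acc_beta(k, 0.0), acc_u(n, 0.0), acc_v(n, 0.0);
  double win_alpha = 0.0;
  std::vector<double> win_beta(k, 0.0), win_u(n, 0.0), win_v(n, 0.0);
  const int win_len = 50;

  NumericMatrix theta_out(n_kept, n);
  NumericVector alpha_out(n_kept), tau_u_out(n_kept), tau_v_out(n_kept);
  NumericMatrix beta_out(n_kept, std::max(k, 1));

  const int n_total = n_burnin + n_iter;
  int kept = 0;

  for (int it = 1; it <= n_total; ++it) {
    bool post = it > n_burnin;

    // alpha
    {
      double d = R::rnorm(0.0, sc_alpha);
      double prop = alpha + d;
      double lr = -(prop * prop - alpha * alpha) / (2.0 * alpha_sd * alpha_sd);
      for (int i = 0; i < n; ++i)
        lr += O[i] * d - E[i] * (std::exp(eta[i] + d) - std::exp(eta[i]));
      if (std::log(R::runif(0.0, 1.0)) < lr) {
        alpha = prop;
        for (int i = 0; i < n; ++i) eta[i] += d;
        win_alpha += 1.0;
        if (post) acc_alpha += 1.0;
      }
    }

    // beta
    for (int j = 0; j < k; ++j) {
      double step = R::rnorm(0.0, sc_beta[j]);
      double prop = beta[j] + step;
      double lr = -(prop * prop - beta[j] * beta[j]) /
        (2.0 * beta_sd * beta_sd);
      for (size_t a = 0; a < active[j].size(); ++a) {
        int i = active[j][a];
        double d = step * X(i, j);
        lr += O[i] * d - E[i] * (std::exp(eta[i] + d) - std::exp(eta[i]));
      }
      if (std::log(R::runif(0.0, 1.0)) < lr) {
        for (size_t a = 0; a < active[j].size(); ++a) {
          int i = active[j][a];
          eta[i] += step * X(i, j);
        }
        beta[j] = prop;
        win_beta[j] += 1.0;
        if (post) acc_beta[j] += 1.0;
      }
    }

    // u
    for (int i = 0; i < n; ++i) {
      double d = R::rnorm(0.0, sc_u[i]);
      double prop = u[i] + d;
      double lr = O[i] * d - E[i] * (std::exp(eta[i] + d) - std::exp(eta[i]))
        - tau_u / 2.0 * (prop * prop - u[i] * u[i]);
      if (std::log(R::runif(0.0, 1.0)) < lr) {
        u[i] = prop; eta[i] += d;
        win_u[i] += 1.0;
        if (post) acc_u[i] += 1.0;
      }
    }

    // v (CAR full conditional prior) + recentring
    if (spatial && n_free > 0) {
      for (int f = 0; f < n_free; ++f) {
        int i = free_ix[f];
        double nb_sum = 0.0;
        int ni = nbr[i].size();
        for (int a = 0; a < ni; ++a) nb_sum += v[nbr[i][a]];
        double mu = nb_sum / ni;
        double prec = tau_v * ni;
        double d = R::rnorm(0.0, sc_v[i]);
        double prop = v[i] + d;
        double lr = O[i] * d - E[i] * (std::exp(eta[i] + d) - std::exp(eta[i]))
          - prec / 2.0 * ((prop - mu) * (prop - mu)
                          - (v[i] - mu) * (v[i] - mu));
        if (std::log(R::runif(0.0, 1.0)) < lr) {
          v[i] = prop; eta[i] += d;
          win_v[i] += 1.0;
          if (post) acc_v[i] += 1.0;
        }
      }
      double m = 0.0;
      for (int f = 0; f < n_free; ++f) m += v[free_ix[f]];
      m /= n_free;
      for (int f = 0; f < n_free; ++f) v[free_ix[f]] -= m;
      alpha += m;
    }

    // precisions (conjugate)
    if (!fix_tau) {
      double ssu = 0.0;
      for (int i = 0; i < n; ++i) ssu += u[i] * u[i];
      tau_u = R::rgamma(hyper_shape + n / 2.0,
                        1.0 / (hyper_rate + ssu / 2.0));
      if (spatial) {
        double ssv = 0.0;
        for (int i = 0; i < n; ++i)
          for (size_t a = 0; a < nbr[i].size(); ++a) {
            int j = nbr[i][a];
            if (j > i) ssv += (v[i] - v[j]) * (v[i] - v[j]);
          }
        tau_v = R::rgamma(hyper_shape + (n - n_components) / 2.0,
                          1.0 / (hyper_rate + ssv / 2.0));
      }
    }

    // burn-in adaptation toward ~0.44 acceptance
    if (adapt && it <= n_burnin && it % win_len == 0) {
      const double target = 0.44;
      sc_alpha *= std::exp(win_alpha / win_len - target);
      win_alpha = 0.0;
      for (int j = 0; j < k; ++j) {
        sc_beta[j] *= std::exp(win_beta[j] / win_len - target);
        win_beta[j] = 0.0;
      }
      for (int i = 0; i < n; ++i) {
        sc_u[i] *= std::exp(win_u[i] / win_len - target);
        win_u[i] = 0.0;
        sc_v[i] *= std::exp(win_v[i] / win_len - target);
        win_v[i] = 0.0;
      }
    }

    if (post && (it - n_burnin) % thin == 0) {
      for (int i = 0; i < n; ++i) theta_out(kept, i) = std::exp(eta[i]);
      alpha_out[kept] = alpha;
      for (int j = 0; j < k; ++j) beta_out(kept, j) = beta[j];
      tau_u_out[kept] = tau_u;
      tau_v_out[kept] = tau_v;
      ++kept;
    }
  }

  List accept = List::create(
    _["alpha"] = acc_alpha / n_iter,
    _["beta"] = NumericVector(acc_beta.begin(), acc_beta.end()) /
      (double)n_iter,
    _["u"] = NumericVector(acc_u.begin(), acc_u.end()) / (double)n_iter,
    _["v"] = NumericVector(acc_v.begin(), acc_v.end()) / (double)n_iter);

  return List::create(
    _["theta"] = theta_out,
    _["alpha"] = alpha_out,
    _["beta"] = beta_out,
    _["tau_u"] = tau_u_out,
    _["tau_v"] = tau_v_out,
    _["accept"] = accept);
}
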