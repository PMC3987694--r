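#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// numerically stable log(1 + exp(x))
static inline double log1pe(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// binomial log-likelihood over all cells (without the constant choose term)
static double loglik_all(const std::vector<double> &eta,
                         const IntegerVector &y, const IntegerVector &m) {
  double ll = 0.0;
  for (int i = 0; i < (int)eta.size(); ++i)
    ll += y[i] * eta[i] - m[i] * log1pe(eta[i]);
  return ll;
}

// Metropolis-within-Gibbs sampler for the hierarchical spatial logistic
// model: logit p = beta0 + X beta + f_s(area) + f_u(area), ICAR prior on
// f_s, iid normal prior on f_u, N(0, 1/tau_beta) priors on (beta0, beta),
// Gamma(a, b) priors on the precisions. Data enter as aggregated binomial
// cells (y successes of m trials per unique area x covariate pattern).
// Random-walk proposals adapt during burn-in only. Uses R's RNG, so draws
// are reproducible under set.seed().
// [[Rcpp::export]]
List bym_mcmc_cpp(IntegerVector y, IntegerVector m, NumericMatrix X,
                  IntegerVector area, int n_areas, List nb_list,
                  IntegerVector comp, int n_comp,
                  bool include_s, bool include_u,
                  double prior_a, double prior_b, double tau_beta,
                  int n_iter, int burn_in, int thin,
                  List init, List updates) {
  const int nc = y.size();
  const int p = X.ncol();

  const bool up_beta  = as<bool>(updates["beta"]);
  const bool up_fs    = include_s && as<bool>(updates["fs"]);
  const bool up_fu    = include_u && as<bool>(updates["fu"]);
  const bool up_tau_s = include_s && as<bool>(updates["tau_s"]);
  const bool up_tau_u = include_u && as<bool>(updates["tau_u"]);

  // neighbour structure
  std::vector< std::vector<int> > nbs(n_areas);
  int n_edges = 0;
  for (int i = 0; i < n_areas; ++i) {
    IntegerVector v = nb_list[i];
    nbs[i] = as< std::vector<int> >(v);
    n_edges += v.size();
  }
  n_edges /= 2;

  // cells per area
  std::vector< std::vector<int> > cells(n_areas);
  for (int i = 0; i < nc; ++i) cells[area[i]].push_back(i);
  // areas per component, component sizes
  std::vector< std::vector<int> > comp_areas(n_comp);
  for (int i = 0; i < n_areas; ++i) comp_areas[comp[i]].push_back(i);

  // state
  double beta0 = as<double>(init["beta0"]);
  NumericVector beta = clone(as<NumericVector>(init["beta"]));
  NumericVector fs = clone(as<NumericVector>(init["fs"]));
  NumericVector fu = clone(as<NumericVector>(init["fu"]));
  double tau_s = as<double>(init["tau_s"]);
  double tau_u = as<double>(init["tau_u"]);

  std::vector<double> eta(nc);
  for (int i = 0; i < nc; ++i) {
    double e = beta0;
    for (int j = 0; j < p; ++j) e += X(i, j) * beta[j];
    e += fs[area[i]] + fu[area[i]];
    eta[i] = e;
  }

  // proposal scales (adapted during burn-in, frozen after)
  double s_b0 = 0.1;
  std::vector<double> s_beta(p, 0.1);
  double s_fs = 0.3, s_fu = 0.3;
  int acc_b0 = 0, try_b0 = 0;
  std::vector<int> acc_beta(p, 0), try_beta(p, 0);
  long acc_fs = 0, try_fs = 0, acc_fu = 0, try_fu = 0;
  long tacc_b0 = 0, ttry_b0 = 0, tacc_beta = 0, ttry_beta = 0;
  long tacc_fs = 0, ttry_fs = 0, tacc_fu = 0, ttry_fu = 0;

  const int n_keep = (n_iter - burn_in) / thin;
  NumericVector out_beta0(n_keep), out_tau_s(n_keep), out_tau_u(n_keep),
                out_dev(n_keep);
  NumericMatrix out_beta(n_keep, p), out_fs(n_keep, n_areas),
                out_fu(n_keep, n_areas);
  int keep = 0;

  const double adapt_every = 50;

  for (int it = 1; it <= n_iter; ++it) {
    if (it % 500 == 0) Rcpp::checkUserInterrupt();

    if (up_beta) {
      // beta0
      {
        double d = R::rnorm(0.0, s_b0);
        double dll = 0.0;
        for (int i = 0; i < nc; ++i)
          dll += y[i] * d - m[i] * (log1pe(eta[i] + d) - log1pe(eta[i]));
        double dlp = -0.5 * tau_beta * ((beta0 + d) * (beta0 + d) - beta0 * beta0);
        ++try_b0; ++ttry_b0;
        if (std::log(R::unif_rand()) < dll + dlp) {
          beta0 += d;
          for (int i = 0; i < nc; ++i) eta[i] += d;
          ++acc_b0; ++tacc_b0;
        }
      }
      // each beta_j
      for (int j = 0; j < p; ++j) {
        double d = R::rnorm(0.0, s_beta[j]);
        double dll = 0.0;
        for (int i = 0; i < nc; ++i) {
          double xij = X(i, j);
          if (xij != 0.0) {
            double de = xij * d;
            dll += y[i] * de - m[i] * (log1pe(eta[i] + de) - log1pe(eta[i]));
          }
        }
        double dlp = -0.5 * tau_beta * ((beta[j] + d) * (beta[j] + d) - beta[j] * beta[j]);
        ++try_beta[j]; ++ttry_beta;
        if (std::log(R::unif_rand()) < dll + dlp) {
          beta[j] += d;
          for (int i = 0; i < nc; ++i) eta[i] += X(i, j) * d;
          ++acc_beta[j]; ++tacc_beta;
        }
      }
    }

    if (up_fs) {
      // single-site random-walk updates, ICAR pairwise-difference prior
      for (int a = 0; a < n_areas; ++a) {
        if (nbs[a].empty()) continue;           // isolated areas pinned at 0
        double d = R::rnorm(0.0, s_fs);
        double dll = 0.0;
        for (int ci : cells[a])
          dll += y[ci] * d - m[ci] * (log1pe(eta[ci] + d) - log1pe(eta[ci]));
        double dq = 0.0;                         // change in sum (f_a - f_j)^2
        double f = fs[a];
        for (int j : nbs[a]) {
          double e_old = f - fs[j], e_new = f + d - fs[j];
          dq += e_new * e_new - e_old * e_old;
        }
        double dlp = -0.5 * tau_s * dq;
        ++try_fs; ++ttry_fs;
        if (std::log(R::unif_rand()) < dll + dlp) {
          fs[a] += d;
          for (int ci : cells[a]) eta[ci] += d;
          ++acc_fs; ++tacc_fs;
        }
      }
      // re-centre per component; with one component the shift is absorbed
      // into beta0 exactly (linear predictor invariant); with several,
      // Besag-style centering-on-the-fly (eta adjusted accordingly)
      if (n_comp == 1) {
        double mn = 0.0;
        for (int a = 0; a < n_areas; ++a) mn += fs[a];
        mn /= n_areas;
        for (int a = 0; a < n_areas; ++a) fs[a] -= mn;
        beta0 += mn;
      } else {
        std::vector<double> mn(n_comp, 0.0);
        for (int k = 0; k < n_comp; ++k) {
          for (int a : comp_areas[k]) mn[k] += fs[a];
          mn[k] /= comp_areas[k].size();
          for (int a : comp_areas[k]) fs[a] -= mn[k];
        }
        for (int i = 0; i < nc; ++i) eta[i] -= mn[comp[area[i]]];
      }
    }

    if (up_fu) {
      for (int a = 0; a < n_areas; ++a) {
        double d = R::rnorm(0.0, s_fu);
        double dll = 0.0;
        for (int ci : cells[a])
          dll += y[ci] * d - m[ci] * (log1pe(eta[ci] + d) - log1pe(eta[ci]));
        double dlp = -0.5 * tau_u * ((fu[a] + d) * (fu[a] + d) - fu[a] * fu[a]);
        ++try_fu; ++ttry_fu;
        if (std::log(R::unif_rand()) < dll + dlp) {
          fu[a] += d;
          for (int ci : cells[a]) eta[ci] += d;
          ++acc_fu; ++tacc_fu;
        }
      }
    }

    if (up_tau_u) {
      double ss = 0.0;
      for (int a = 0; a < n_areas; ++a) ss += fu[a] * fu[a];
      tau_u = R::rgamma(prior_a + 0.5 * n_areas, 1.0 / (prior_b + 0.5 * ss));
    }
    if (up_tau_s) {
      double ss = 0.0;
      for (int a = 0; a < n_areas; ++a)
        for (int j : nbs[a])
          if (j > a) { double e = fs[a] - fs[j]; ss += e * e; }
      tau_s = R::rgamma(prior_a + 0.5 * (n_areas - n_comp),
                        1.0 / (prior_b + 0.5 * ss));
    }

    // adapt proposal scales during burn-in, targeting ~35% acceptance
    if (it <= burn_in && it % (int)adapt_every == 0) {
      auto tune = [](double s, double rate) {
        s *= std::exp(0.8 * (rate - 0.35));
        if (s < 1e-3) s = 1e-3;
        if (s > 10.0) s = 10.0;
        return s;
      };
      if (try_b0 > 0) { s_b0 = tune(s_b0, (double)acc_b0 / try_b0); acc_b0 = try_b0 = 0; }
      for (int j = 0; j < p; ++j)
        if (try_beta[j] > 0) {
          s_beta[j] = tune(s_beta[j], (double)acc_beta[j] / try_beta[j]);
          acc_beta[j] = try_beta[j] = 0;
        }
      if (try_fs > 0) { s_fs = tune(s_fs, (double)acc_fs / try_fs); acc_fs = try_fs = 0; }
      if (try_fu > 0) { s_fu = tune(s_fu, (double)acc_fu / try_fu); acc_fu = try_fu = 0; }
    }

    if (it > burn_in && (it - burn_in) % thin == 0 && keep < n_keep) {
      double ll = loglik_all(eta, y, m);
      if (!std::isfinite(ll))
        stop("divergence: non-finite log-likelihood at iteration %d", it);
      out_beta0[keep] = beta0;
      for (int j = 0; j < p; ++j) out_beta(keep, j) = beta[j];
      for (int a = 0; a < n_areas; ++a) {
        out_fs(keep, a) = fs[a];
        out_fu(keep, a) = fu[a];
      }
      out_tau_s[keep] = tau_s;
      out_tau_u[keep] = tau_u;
      out_dev[keep] = -2.0 * ll;
      ++keep;
    }
  }

  return List::create(
    _["beta0"] = out_beta0, _["beta"] = out_beta,
    _["f_s"] = out_fs, _["f_u"] = out_fu,
    _["tau_s"] = out_tau_s, _["tau_u"] = out_tau_u,
    _["deviance"] = out_dev,
    _["acceptance_rates"] = List::create(
      _["beta0"] = ttry_b0 ? (double)tacc_b0 / ttry_b0 : NA_REAL,
      _["beta"] = ttry_beta ? (double)tacc_beta / ttry_beta : NA_REAL,
      _["f_s"] = ttry_fs ? (double)tacc_fs / ttry_fs : NA_REAL,
      _["f_u"] = ttry_fu ? (double)tacc_fu / ttry_fu : NA_REAL),
    _["scales"] = List::create(_["beta0"] = s_b0, _["beta"] = s_beta,
                               _["f_s"] = s_fs, _["f_u"] = s_fu));
}
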