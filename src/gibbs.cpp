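// Single-site Gibbs sampler for Bayesian mixture models of the form
//   y = X b + sum_t M_t q_t + Z l + e
// with fixed birth-year effects b (flat prior), random litter effects
// l ~ N(0, s2l), per-SNP effects q_t under a four-component normal mixture
// with known mixing proportions and estimated, ordered class variances,
// and residuals e ~ N(0, s2e).  Flat priors on the variances give scaled
// inverse-chi-square full conditionals with df = k - 2, which is improper
// for k <= 2 assigned effects; that case falls back to a uniform redraw
// between the neighbouring class variances.
//
// Uses R's RNG throughout so that set.seed() in R fixes the chain.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// One class variance under the ordering constraint lower < cv < upper,
// by rejection (up to 100 redraws, else keep the previous value).
//
// Under the flat prior the conditional is S / chisq(k - 2), improper for
// k <= 2 and with an infinite mean for k <= 4 (and infinite variance for
// k <= 6): sparsely populated classes would inject heavy-tailed spikes into
// the posterior means of the genetic variance components, which are linear
// in the class variances. Classes with fewer than 7 assigned effects are
// therefore redrawn uniformly between their neighbours, with at most one
// octave (x2) of headroom away from the nearest populated side: an empty
// class may sit up to 2x above its lower neighbour (top/interior) or down to
// 1/2 of its upper neighbour (bottom). Unbounded or state-tracking bounds
// are unstable here - chained uniform redraws of several empty classes
// either ratchet the ladder upwards without limit or contract it
// irreversibly - and generous headroom leaks straight into the genetic
// variance components, which are linear in the class variances with the
// prior mixing proportions as weights. One octave keeps an empty class
// distinguishable from its neighbour, so the indicator step can re-populate
// it and the proper conditional can then carry it to the data scale, while
// perturbing the variance decomposition as little as possible.
static double sample_class_variance(double ss, int k, double cv_old,
                                    double lower, double upper,
                                    bool bottom_class, bool top_class,
                                    double floor_val) {
  if (k >= 7) {
    for (int tries = 0; tries < 100; ++tries) {
      double cand = ss / R::rchisq((double)(k - 2));
      if (cand > lower && cand < upper && cand > floor_val) return cand;
    }
    return cv_old;
  }
  double lo, hi;
  if (top_class) {
    lo = std::max(lower, floor_val);
    hi = 2.0 * lo;
  } else if (bottom_class) {
    hi = upper;
    lo = std::max(upper / 2.0, floor_val);
  } else {
    lo = std::max(lower, floor_val);
    hi = std::min(upper, 2.0 * lo);
  }
  if (hi <= lo) hi = lo + std::max(lo * 1e-6, floor_val);
  return R::runif(lo, hi);
}

// [[Rcpp::export(name = ".gibbs_sampler_cpp")]]
List gibbs_sampler_cpp(const arma::vec& y,
                       const arma::ivec& year,    // 0-based
                       const arma::ivec& litter,  // 0-based
                       int n_year, int n_litter,
                       const List& M_list,        // per-effect n x m matrices
                       const arma::vec& pi,
                       int n_iter, int burn_in, int thin,
                       List init,
                       bool update_b,
                       bool update_l,
                       bool update_class_var,
                       bool update_sigma2_l,
                       bool update_sigma2_e,
                       double var_floor,
                       int resync_every) {
  const int n = y.n_elem;
  const int n_eff = M_list.size();
  const int n_class = pi.n_elem;

  std::vector<arma::mat> M(n_eff);
  std::vector<arma::vec> css(n_eff);
  int m = 0;
  for (int t = 0; t < n_eff; ++t) {
    M[t] = as<arma::mat>(M_list[t]);
    m = M[t].n_cols;
    css[t] = arma::sum(arma::square(M[t]), 0).t();
  }

  // --- state ---
  arma::vec b = as<arma::vec>(init["b"]);
  arma::vec l = as<arma::vec>(init["l"]);
  std::vector<arma::vec> q(n_eff);
  std::vector<arma::ivec> delta(n_eff);   // 0-based class index per SNP
  std::vector<arma::vec> cv(n_eff);
  {
    List q0 = init["q"], d0 = init["delta"], cv0 = init["class_var"];
    for (int t = 0; t < n_eff; ++t) {
      q[t] = as<arma::vec>(q0[t]);
      delta[t] = as<arma::ivec>(d0[t]);
      cv[t] = as<arma::vec>(cv0[t]);
    }
  }
  double s2l = as<double>(init["sigma2_l"]);
  double s2e = as<double>(init["sigma2_e"]);

  // residuals from scratch
  arma::vec r = y;
  for (int i = 0; i < n; ++i) r[i] -= b[year[i]] + l[litter[i]];
  for (int t = 0; t < n_eff; ++t) r -= M[t] * q[t];

  // group sizes
  arma::vec n_per_year(n_year, arma::fill::zeros);
  arma::vec n_per_litter(n_litter, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    n_per_year[year[i]] += 1.0;
    n_per_litter[litter[i]] += 1.0;
  }

  // --- storage ---
  const int n_save = (burn_in < n_iter) ? (n_iter - burn_in) / thin : 0;
  const int n_par = 2 + n_class * n_eff;   // s2e, s2l, class variances
  arma::mat samples(std::max(n_save, 1), n_par, arma::fill::zeros);
  std::vector<arma::vec> q_sum(n_eff), q_sumsq(n_eff);
  for (int t = 0; t < n_eff; ++t) {
    q_sum[t] = arma::vec(m, arma::fill::zeros);
    q_sumsq[t] = arma::vec(m, arma::fill::zeros);
  }
  arma::vec b_sum(n_year, arma::fill::zeros);
  arma::vec l_sum(std::max(n_litter, 1), arma::fill::zeros);
  arma::vec inv_dens(n, arma::fill::zeros);
  arma::vec fitted_sum(n, arma::fill::zeros);
  double max_resync = 0.0;
  int saved = 0;

  arma::vec grp_sum(std::max(n_year, std::max(n_litter, 1)));
  arma::vec grp_diff(grp_sum.n_elem);
  arma::vec logl(n_class);

  for (int iter = 1; iter <= n_iter; ++iter) {
    if (iter % 512 == 0) Rcpp::checkUserInterrupt();

    // (1) birth-year effects, flat prior: b_k | . ~ N(rhs/n_k, s2e/n_k)
    if (update_b) {
    grp_sum.zeros();
    for (int i = 0; i < n; ++i) grp_sum[year[i]] += r[i];
    for (int k = 0; k < n_year; ++k) {
      if (n_per_year[k] < 0.5) { grp_diff[k] = 0.0; continue; }
      double mean = grp_sum[k] / n_per_year[k] + b[k];
      double bnew = mean + std::sqrt(s2e / n_per_year[k]) * norm_rand();
      grp_diff[k] = bnew - b[k];
      b[k] = bnew;
    }
    for (int i = 0; i < n; ++i) r[i] -= grp_diff[year[i]];
    }

    // (2) litter effects: l_j | . ~ N(rhs/(n_j + lam), s2e/(n_j + lam))
    if (update_l && n_litter > 0) {
      double lam = s2e / s2l;
      grp_sum.zeros();
      for (int i = 0; i < n; ++i) grp_sum[litter[i]] += r[i];
      for (int j = 0; j < n_litter; ++j) {
        double denom = n_per_litter[j] + lam;
        double mean = (grp_sum[j] + n_per_litter[j] * l[j]) / denom;
        double lnew = mean + std::sqrt(s2e / denom) * norm_rand();
        grp_diff[j] = lnew - l[j];
        l[j] = lnew;
      }
      for (int i = 0; i < n; ++i) r[i] -= grp_diff[litter[i]];
    }

    // (3) SNP effects: class indicator from the effect-integrated marginal
    //     likelihood, then the effect from its normal full conditional.
    for (int t = 0; t < n_eff; ++t) {
      const arma::mat& Mt = M[t];
      for (int j = 0; j < m; ++j) {
        const double C = css[t][j];
        const double q_old = q[t][j];
        if (C < 1e-12) { q[t][j] = 0.0; continue; }
        const double rhs = arma::dot(Mt.col(j), r) + C * q_old;

        // marginally rhs ~ N(0, C^2 cv_c + C s2e) under class c
        double lmax = -arma::datum::inf;
        for (int c = 0; c < n_class; ++c) {
          if (pi[c] <= 0.0) { logl[c] = -arma::datum::inf; continue; }
          double v = C * C * cv[t][c] + C * s2e;
          logl[c] = std::log(pi[c]) - 0.5 * std::log(v) - 0.5 * rhs * rhs / v;
          if (logl[c] > lmax) lmax = logl[c];
        }
        double wsum = 0.0;
        for (int c = 0; c < n_class; ++c) {
          logl[c] = (logl[c] > -arma::datum::inf) ? std::exp(logl[c] - lmax) : 0.0;
          wsum += logl[c];
        }
        double u = unif_rand() * wsum;
        int cls = 0;
        for (; cls < n_class - 1; ++cls) {
          u -= logl[cls];
          if (u <= 0.0) break;
        }
        delta[t][j] = cls;

        const double denom = C + s2e / cv[t][cls];
        const double mean = rhs / denom;
        const double qnew = mean + std::sqrt(s2e / denom) * norm_rand();
        q[t][j] = qnew;
        if (qnew != q_old) r -= Mt.col(j) * (qnew - q_old);
      }
    }

    // (4) class variances, ordered, flat prior
    if (update_class_var) {
      for (int t = 0; t < n_eff; ++t) {
        for (int c = 0; c < n_class; ++c) {
          int k = 0; double ss = 0.0;
          for (int j = 0; j < m; ++j) {
            if (delta[t][j] == c) { ++k; ss += q[t][j] * q[t][j]; }
          }
          double lower = (c > 0) ? cv[t][c - 1] : var_floor;
          double upper = (c < n_class - 1) ? cv[t][c + 1] : arma::datum::inf;
          cv[t][c] = sample_class_variance(ss, k, cv[t][c], lower, upper,
                                           c == 0, c == n_class - 1,
                                           var_floor);
        }
      }
    }

    // (5) litter and residual variances, flat priors
    if (update_sigma2_l && n_litter >= 3) {
      s2l = arma::dot(l, l) / R::rchisq((double)(n_litter - 2));
      if (s2l < var_floor) s2l = var_floor;
    }
    if (update_sigma2_e) {
      s2e = arma::dot(r, r) / R::rchisq((double)(n - 2));
      if (s2e < var_floor) s2e = var_floor;
    }

    // periodic residual resynchronization
    if (resync_every > 0 && iter % resync_every == 0) {
      arma::vec r2 = y;
      for (int i = 0; i < n; ++i) r2[i] -= b[year[i]] + l[litter[i]];
      for (int t = 0; t < n_eff; ++t) r2 -= M[t] * q[t];
      double d = arma::abs(r - r2).max();
      if (d > max_resync) max_resync = d;
      r = r2;
    }

    if (!R_finite(s2e) || !R_finite(arma::accu(r)))
      stop("non-finite state at iteration %d", iter);

    // --- save ---
    if (iter > burn_in && (iter - burn_in) % thin == 0 && saved < n_save) {
      samples(saved, 0) = s2e;
      samples(saved, 1) = s2l;
      for (int t = 0; t < n_eff; ++t)
        for (int c = 0; c < n_class; ++c)
          samples(saved, 2 + t * n_class + c) = cv[t][c];
      for (int t = 0; t < n_eff; ++t) {
        q_sum[t] += q[t];
        q_sumsq[t] += arma::square(q[t]);
      }
      b_sum += b;
      if (n_litter > 0) l_sum += l;
      const double sd = std::sqrt(s2e);
      for (int i = 0; i < n; ++i) {
        inv_dens[i] += 1.0 / R::dnorm(r[i], 0.0, sd, 0);
        fitted_sum[i] += y[i] - r[i];
      }
      ++saved;
    }
  }

  // posterior summaries
  List q_mean(n_eff), q_sd(n_eff), q_list(n_eff), delta_list(n_eff), cv_list(n_eff);
  for (int t = 0; t < n_eff; ++t) {
    arma::vec mu = q_sum[t] / std::max(saved, 1);
    arma::vec v = q_sumsq[t] / std::max(saved, 1) - arma::square(mu);
    v.transform([](double x) { return x > 0 ? std::sqrt(x) : 0.0; });
    q_mean[t] = mu;
    q_sd[t] = v;
    q_list[t] = q[t];
    delta_list[t] = delta[t];
    cv_list[t] = cv[t];
  }
  arma::vec cpo(n);
  for (int i = 0; i < n; ++i)
    cpo[i] = (saved > 0 && inv_dens[i] > 0) ? saved / inv_dens[i] : NA_REAL;

  List state = List::create(
    _["b"] = b, _["l"] = l, _["q"] = q_list, _["delta"] = delta_list,
    _["class_var"] = cv_list, _["sigma2_l"] = s2l, _["sigma2_e"] = s2e,
    _["residuals"] = r);

  return List::create(
    _["samples"] = samples.rows(0, std::max(saved - 1, 0)),
    _["q_mean"] = q_mean,
    _["q_sd"] = q_sd,
    _["b_mean"] = b_sum / std::max(saved, 1),
    _["l_mean"] = l_sum / std::max(saved, 1),
    _["cpo"] = cpo,
    _["fitted_mean"] = fitted_sum / std::max(saved, 1),
    _["max_resync_diff"] = max_resync,
    _["n_saved"] = saved,
    _["state"] = state);
}
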