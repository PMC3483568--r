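// Adaptive Gaussian random-walk Metropolis for the power-prior posterior.
//
// Parameter vector theta = (b0, b1, b2, b3, t) with the NB size mapped to
// the reals through r = r_lo + exp(t); the Jacobian term t is included in
// the target.  Proposal covariance and scale adapt during burn-in only
// (Haario empirical covariance + Robbins-Monro scale toward a target
// acceptance rate) and are frozen afterwards so the retained chain is
// Markov.  Uses R's RNG, so draws are reproducible under set.seed().

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

// For integer y the rising-factorial term is accumulated as
// sum_j log(r + j), which stays exact for arbitrarily large r (the
// lgamma difference cancels catastrophically there); the size term uses
// log1p(mu / r) for the same reason, so the Poisson limit is clean.
double nb_lpmf(double y, double mu, double r) {
  double lrf;
  if (y <= 128.0) {
    lrf = 0.0;
    for (int j = 0; j < static_cast<int>(y); ++j) lrf += std::log(r + j);
    lrf -= R::lgammafn(y + 1.0);
  } else {
    lrf = R::lgammafn(y + r) - R::lgammafn(r) - R::lgammafn(y + 1.0);
  }
  return lrf - r * std::log1p(mu / r) + y * (std::log(mu) - std::log(r + mu));
}

struct Trial {
  const double *y, *med, *mj, *off;
  int n;
};

double trial_loglik(const Trial& d, const double* b, double r) {
  double ll = 0.0;
  for (int i = 0; i < d.n; ++i) {
    double eta = b[0] + b[1] * d.med[i] + b[2] * d.mj[i] +
                 b[3] * d.med[i] * d.mj[i] + d.off[i];
    ll += nb_lpmf(d.y[i], std::exp(eta), r);
  }
  return ll;
}

// Cholesky of a small SPD matrix (row-major d x d); returns false if it
// fails, in which case the caller keeps the previous factor.
bool cholesky(const std::vector<double>& a, int d, std::vector<double>& L) {
  L.assign(d * d, 0.0);
  for (int i = 0; i < d; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = a[i * d + j];
      for (int k = 0; k < j; ++k) s -= L[i * d + k] * L[j * d + k];
      if (i == j) {
        if (s <= 0.0) return false;
        L[i * d + i] = std::sqrt(s);
      } else {
        L[i * d + j] = s / L[j * d + j];
      }
    }
  }
  return true;
}

}  // namespace

// [[Rcpp::export]]
double nb_loglik_cpp(NumericVector y, NumericVector med, NumericVector mj,
                     NumericVector off, NumericVector beta, double r) {
  Trial d{REAL(y), REAL(med), REAL(mj), REAL(off),
          static_cast<int>(y.size())};
  return trial_loglik(d, REAL(beta), r);
}

// [[Rcpp::export]]
List rw_metropolis_cpp(NumericVector y_c, NumericVector med_c,
                       NumericVector mj_c, NumericVector off_c,
                       NumericVector y_h, NumericVector med_h,
                       NumericVector mj_h, NumericVector off_h, double a0,
                       NumericVector init, LogicalVector free_mask,
                       double coef_mean, double coef_sd, double r_lo,
                       double log_inv_width, int n_burn, int n_keep,
                       int thin, int adapt_window, double target_accept) {
  const Trial cur{REAL(y_c), REAL(med_c), REAL(mj_c), REAL(off_c),
                  static_cast<int>(y_c.size())};
  const Trial hist{REAL(y_h), REAL(med_h), REAL(mj_h), REAL(off_h),
                   static_cast<int>(y_h.size())};
  const bool use_hist = a0 > 0.0 && hist.n > 0;

  std::vector<double> th(init.begin(), init.end());  // length 5
  std::vector<int> free_idx;
  for (int j = 0; j < 5; ++j)
    if (free_mask[j]) free_idx.push_back(j);
  const int d = static_cast<int>(free_idx.size());

  auto logpost = [&](const double* theta) -> double {
    double t = theta[4];
    double r = r_lo + std::exp(t);
    if (!R_FINITE(r)) return R_NegInf;
    double lp = trial_loglik(cur, theta, r);
    if (use_hist) lp += a0 * trial_loglik(hist, theta, r);
    for (int j = 0; j < 4; ++j)
      lp += R::dnorm(theta[j], coef_mean, coef_sd, 1);
    lp += -2.0 * std::log(r) - log_inv_width;  // Uniform(l,u) prior on 1/r
    lp += t;                                   // Jacobian of r = r_lo + e^t
    return lp;
  };

  double lp_cur = logpost(th.data());
  if (!R_FINITE(lp_cur)) stop("non-finite log-posterior at initialization");

  // Proposal: theta_free' = theta_free + lambda * L z.
  std::vector<double> L(d * d, 0.0), cov(d * d, 0.0);
  for (int i = 0; i < d; ++i) L[i * d + i] = 0.05;
  double log_lambda = 0.0;

  // Online mean / scatter of burn-in samples (Welford).
  std::vector<double> mean(d, 0.0), scat(d * d, 0.0), delta(d), z(d), prop(5);
  long n_seen = 0;
  int win_acc = 0, n_windows = 0;
  const double chol_scale = 2.38 * 2.38 / std::max(d, 1);

  bool cov_adapted = false;
  long kept = 0, acc_keep = 0;
  NumericMatrix draws(n_keep, 5);
  const long total = static_cast<long>(n_burn) +
                     static_cast<long>(n_keep) * thin;

  for (long iter = 0; iter < total; ++iter) {
    const bool burning = iter < n_burn;
    // propose
    for (int i = 0; i < d; ++i) z[i] = R::norm_rand();
    const double lam = std::exp(log_lambda);
    prop.assign(th.begin(), th.end());
    for (int i = 0; i < d; ++i) {
      double step = 0.0;
      for (int k = 0; k <= i; ++k) step += L[i * d + k] * z[k];
      prop[free_idx[i]] += lam * step;
    }
    double lp_prop = logpost(prop.data());
    bool accept = R_FINITE(lp_prop) &&
                  std::log(R::unif_rand()) < lp_prop - lp_cur;
    if (accept) {
      th.assign(prop.begin(), prop.end());
      lp_cur = lp_prop;
    }

    if (burning) {
      if (accept) ++win_acc;
      // update running moments with the current state
      ++n_seen;
      for (int i = 0; i < d; ++i) {
        delta[i] = th[free_idx[i]] - mean[i];
        mean[i] += delta[i] / n_seen;
      }
      for (int i = 0; i < d; ++i)
        for (int j = 0; j <= i; ++j) {
          double upd = delta[i] * (th[free_idx[j]] - mean[j]);
          scat[i * d + j] += upd;
          if (i != j) scat[j * d + i] += upd;
        }
      if ((iter + 1) % adapt_window == 0) {
        ++n_windows;
        double rate = static_cast<double>(win_acc) / adapt_window;
        log_lambda += (rate - target_accept) / std::sqrt((double)n_windows);
        win_acc = 0;
        if (n_seen > 10 * d) {
          for (int i = 0; i < d; ++i)
            for (int j = 0; j < d; ++j) {
              cov[i * d + j] = chol_scale * scat[i * d + j] / (n_seen - 1);
              if (i == j) cov[i * d + j] += 1e-8;
            }
          std::vector<double> Lnew;
          if (cholesky(cov, d, Lnew)) {
            L.swap(Lnew);
            if (!cov_adapted) {  // re-center scale on first covariance swap
              log_lambda = 0.0;
              cov_adapted = true;
            }
          }
        }
      }
    } else {
      long post = iter - n_burn;
      if (accept) ++acc_keep;
      if ((post + 1) % thin == 0) {
        for (int j = 0; j < 4; ++j) draws(kept, j) = th[j];
        draws(kept, 4) = r_lo + std::exp(th[4]);
        ++kept;
      }
    }
    if (iter % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  double keep_iters = static_cast<double>(n_keep) * thin;
  return List::create(
      _["draws"] = draws,
      _["accept_rate"] = keep_iters > 0 ? acc_keep / keep_iters : NA_REAL);
}
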