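#include <Rcpp.h>
using namespace Rcpp;

// Adaptive random-walk Metropolis sampler for the two-parameter BLRM
//   logit p(d) = log_alpha + exp(log_beta) * log(d / d_ref)
// with binomial counts per dose level. Priors are either a bivariate normal
// on (log_alpha, log_beta) or independent two-component normal mixtures per
// parameter (robust mixture prior, marginalized log-sum-exp density).
//
// Uses R's RNG so that set.seed() in R makes fits reproducible.

static inline double log1p_exp(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

static inline double log_mix_norm(double x, double w, double mu1, double sd1,
                                  double mu2, double sd2) {
  // log( w * N(x; mu1, sd1) + (1 - w) * N(x; mu2, sd2) )
  if (w >= 1.0) return R::dnorm(x, mu1, sd1, 1);
  if (w <= 0.0) return R::dnorm(x, mu2, sd2, 1);
  double l1 = std::log(w) + R::dnorm(x, mu1, sd1, 1);
  double l2 = std::log1p(-w) + R::dnorm(x, mu2, sd2, 1);
  double m = std::max(l1, l2);
  return m + std::log(std::exp(l1 - m) + std::exp(l2 - m));
}

struct Posterior {
  const IntegerVector &y, &n;
  const NumericVector &x;        // log(dose / reference_dose) per level
  int prior_type;                // 0 = bivariate normal, 1 = per-param mixture
  const NumericVector &pp;       // prior parameters, see R wrapper

  double log_prior(double la, double lb) const {
    if (prior_type == 0) {
      // pp: mu_a, mu_b, var_a, var_b, cov
      double da = la - pp[0], db = lb - pp[1];
      double det = pp[2] * pp[3] - pp[4] * pp[4];
      return -0.5 * (da * da * pp[3] - 2.0 * da * db * pp[4] + db * db * pp[2]) / det;
    }
    // pp: delta_a, mu_sa, sd_sa, mu_wa, sd_wa, delta_b, mu_sb, sd_sb, mu_wb, sd_wb
    return log_mix_norm(la, pp[0], pp[1], pp[2], pp[3], pp[4]) +
           log_mix_norm(lb, pp[5], pp[6], pp[7], pp[8], pp[9]);
  }

  double log_lik(double la, double lb) const {
    double beta = std::exp(lb), ll = 0.0;
    for (int k = 0; k < x.size(); ++k) {
      if (n[k] == 0) continue;
      double eta = la + beta * x[k];
      ll += y[k] * eta - n[k] * log1p_exp(eta);
    }
    return ll;
  }

  double operator()(double la, double lb) const {
    return log_lik(la, lb) + log_prior(la, lb);
  }
};

// [[Rcpp::export(name = ".blrm_mh_cpp")]]
List blrm_mh_cpp(IntegerVector y, IntegerVector n, NumericVector x,
                 int prior_type, NumericVector prior_pars,
                 NumericMatrix init, NumericVector prop_scale,
                 int warmup, int iter, int thin) {
  const int chains = init.nrow();
  Posterior post{y, n, x, prior_type, prior_pars};

  NumericMatrix la_out(iter, chains), lb_out(iter, chains);
  NumericVector accept(chains);

  for (int c = 0; c < chains; ++c) {
    double la = init(c, 0), lb = init(c, 1);
    double lp = post(la, lb);

    // proposal: lambda * chol(Sigma); Sigma starts at the prior's marginal
    // scales (handles badly conditioned priors) and is adapted from the
    // warmup history
    double log_lambda = std::log(1.0);
    double l11 = prop_scale[0], l21 = 0.0, l22 = prop_scale[1];
    double m1 = la, m2 = lb;                        // running means
    double c11 = prop_scale[0] * prop_scale[0], c12 = 0.0,
           c22 = prop_scale[1] * prop_scale[1];     // running covariance * (t-1)
    int n_acc_keep = 0;

    const int keep_total = warmup + iter * thin;
    int kept = 0;
    for (int t = 1; t <= keep_total; ++t) {
      bool adapting = t <= warmup;
      double lam = std::exp(log_lambda);
      double z1 = R::norm_rand(), z2 = R::norm_rand();
      double pla = la + lam * l11 * z1;
      double plb = lb + lam * (l21 * z1 + l22 * z2);
      double plp = post(pla, plb);
      double dlp = plp - lp;
      double acc_prob = dlp >= 0.0 ? 1.0 : std::exp(dlp);
      if (R::unif_rand() < acc_prob) {
        la = pla; lb = plb; lp = plp;
        if (!adapting) ++n_acc_keep;
      }
      if (adapting) {
        log_lambda += std::pow((double)t, -0.6) * (acc_prob - 0.35);
        // Welford update of the empirical covariance of the warmup path
        double d1 = la - m1, d2 = lb - m2;
        m1 += d1 / t; m2 += d2 / t;
        c11 += d1 * (la - m1); c12 += d1 * (lb - m2); c22 += d2 * (lb - m2);
        if (t >= 50 && t % 25 == 0) {
          double s11 = c11 / (t - 1) + 1e-10, s12 = c12 / (t - 1),
                 s22 = c22 / (t - 1) + 1e-10;
          l11 = std::sqrt(s11);
          l21 = s12 / l11;
          double rem = s22 - l21 * l21;
          l22 = std::sqrt(rem > 1e-12 ? rem : 1e-12);
        }
      } else if ((t - warmup) % thin == 0) {
        la_out(kept, c) = la;
        lb_out(kept, c) = lb;
        ++kept;
      }
    }
    accept[c] = (double)n_acc_keep / (iter * thin);
  }

  return List::create(_["log_alpha"] = la_out, _["log_beta"] = lb_out,
                      _["accept_rate"] = accept);
}
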