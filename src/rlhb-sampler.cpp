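// Hierarchical delta-rule/softmax model: likelihood and MCMC chain runner.
//
// Model per subject i with trials t:
//   Q_chosen(t) = Q_chosen(t-1) + alpha_i * (R(t) - Q_chosen(t-1))
//   P(A at t)   = exp(beta_i Q_A) / (exp(beta_i Q_A) + exp(beta_i Q_B))
//   alpha_i ~ Normal(mu_alpha, sigma_alpha) truncated to [0, 1]
//   beta_i  ~ Normal(mu_beta,  sigma_beta)  truncated to [0, beta_max]
//   mu_alpha ~ U(0,1), sigma_alpha ~ U(0,1), mu_beta ~ U(0,10),
//   sigma_beta ~ U(0,5)   (bounds configurable)
//
// Sampler: random-walk Metropolis within Gibbs, per-parameter Gaussian
// proposals adapted toward 0.44 acceptance during burn-in only. Uses R's
// RNG, so runs are reproducible under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

// log-likelihood of one subject's choice sequence under (alpha, beta)
static double subj_loglik(const IntegerVector& ch, const IntegerVector& rw,
                          double alpha, double beta, double q0) {
  double qa = q0, qb = q0, ll = 0.0;
  const int n = ch.size();
  for (int t = 0; t < n; ++t) {
    double m = std::max(beta * qa, beta * qb);
    double ea = std::exp(beta * qa - m), eb = std::exp(beta * qb - m);
    double pa = ea / (ea + eb);
    double p = (ch[t] == 1) ? pa : 1.0 - pa;
    ll += std::log(p);
    if (ch[t] == 1) qa += alpha * (rw[t] - qa);
    else            qb += alpha * (rw[t] - qb);
  }
  return ll;
}

// [[Rcpp::export]]
double cpp_loglik(List choices, List rewards, NumericVector alpha,
                  NumericVector beta, double q0) {
  const int S = choices.size();
  double ll = 0.0;
  for (int i = 0; i < S; ++i) {
    IntegerVector ch = choices[i], rw = rewards[i];
    ll += subj_loglik(ch, rw, alpha[i], beta[i], q0);
  }
  return ll;
}

// log of the truncated-normal normalizing constant over [lo, hi]
static inline double log_trunc_z(double mu, double sig, double lo, double hi) {
  double z = R::pnorm(hi, mu, sig, 1, 0) - R::pnorm(lo, mu, sig, 1, 0);
  if (z <= 0.0) return -INFINITY;
  return std::log(z);
}

// full truncated-normal log density (needed when mu/sigma change)
static inline double log_dtnorm(double x, double mu, double sig,
                                double lo, double hi) {
  if (x < lo || x > hi || sig <= 0.0) return -INFINITY;
  return R::dnorm(x, mu, sig, 1) - log_trunc_z(mu, sig, lo, hi);
}

struct Adapt {
  double sd;
  int acc, tries;
  Adapt() : sd(0.1), acc(0), tries(0) {}
  void tune() {
    if (tries == 0) return;
    double rate = (double)acc / tries;
    sd *= std::exp(rate - 0.44);
    sd = std::min(std::max(sd, 1e-4), 10.0);
    acc = 0; tries = 0;
  }
};

// One MCMC chain. Returns retained-draws matrix with columns
// (mu_alpha, sigma_alpha, mu_beta, sigma_beta, alpha_1..S, beta_1..S).
// [[Rcpp::export]]
NumericMatrix cpp_rlhb_chain(List choices, List rewards, double q0,
                             int n_iter, int burn_in, int thin,
                             NumericVector mu_alpha_prior,
                             NumericVector sigma_alpha_prior,
                             NumericVector mu_beta_prior,
                             NumericVector sigma_beta_prior,
                             double alpha_lo, double alpha_hi,
                             double beta_lo, double beta_hi,
                             bool use_likelihood) {
  const int S = choices.size();
  const int n_keep = (n_iter - burn_in) / thin;
  NumericMatrix out(n_keep, 4 + 2 * S);

  // initial values drawn from the middle of the priors
  double mu_a = R::runif(0.3, 0.7);
  double sig_a = R::runif(0.1, 0.4);
  double mu_b = R::runif(mu_beta_prior[0] + 0.2 * (mu_beta_prior[1] - mu_beta_prior[0]),
                         mu_beta_prior[0] + 0.6 * (mu_beta_prior[1] - mu_beta_prior[0]));
  double sig_b = R::runif(0.5, 2.0);
  std::vector<double> alpha(S), beta(S), ll(S);
  for (int i = 0; i < S; ++i) {
    alpha[i] = R::runif(0.2, 0.8);
    beta[i] = R::runif(beta_lo + 0.1 * (beta_hi - beta_lo),
                       beta_lo + 0.6 * (beta_hi - beta_lo));
    IntegerVector ch = choices[i], rw = rewards[i];
    ll[i] = use_likelihood ? subj_loglik(ch, rw, alpha[i], beta[i], q0) : 0.0;
  }

  std::vector<Adapt> ad_a(S), ad_b(S);
  Adapt ad_mu_a, ad_sig_a, ad_mu_b, ad_sig_b;
  ad_mu_b.sd = 0.5; ad_sig_b.sd = 0.5;
  for (int i = 0; i < S; ++i) ad_b[i].sd = 0.5;

  int keep = 0;
  for (int it = 1; it <= n_iter; ++it) {
    // subject-level updates; normalizing constant cancels (same mu, sigma)
    for (int i = 0; i < S; ++i) {
      IntegerVector ch = choices[i], rw = rewards[i];
      // alpha_i
      {
        double prop = alpha[i] + R::norm_rand() * ad_a[i].sd;
        ad_a[i].tries++;
        if (prop >= alpha_lo && prop <= alpha_hi) {
          double ll_new = use_likelihood ?
            subj_loglik(ch, rw, prop, beta[i], q0) : 0.0;
          double lr = ll_new - ll[i]
            - 0.5 * std::pow((prop - mu_a) / sig_a, 2)
            + 0.5 * std::pow((alpha[i] - mu_a) / sig_a, 2);
          if (std::log(R::unif_rand()) < lr) {
            alpha[i] = prop; ll[i] = ll_new; ad_a[i].acc++;
          }
        }
      }
      // beta_i
      {
        double prop = beta[i] + R::norm_rand() * ad_b[i].sd;
        ad_b[i].tries++;
        if (prop >= beta_lo && prop <= beta_hi) {
          double ll_new = use_likelihood ?
            subj_loglik(ch, rw, alpha[i], prop, q0) : 0.0;
          double lr = ll_new - ll[i]
            - 0.5 * std::pow((prop - mu_b) / sig_b, 2)
            + 0.5 * std::pow((beta[i] - mu_b) / sig_b, 2);
          if (std::log(R::unif_rand()) < lr) {
            beta[i] = prop; ll[i] = ll_new; ad_b[i].acc++;
          }
        }
      }
    }

    // hyperparameter updates (truncation constants do not cancel here)
    auto hyper_lp = [&](double mu, double sig, const std::vector<double>& x,
                        double lo, double hi) {
      double lp = 0.0;
      for (size_t i = 0; i < x.size(); ++i)
        lp += log_dtnorm(x[i], mu, sig, lo, hi);
      return lp;
    };
    {
      double prop = mu_a + R::norm_rand() * ad_mu_a.sd;
      ad_mu_a.tries++;
      if (prop >= mu_alpha_prior[0] && prop <= mu_alpha_prior[1]) {
        double lr = hyper_lp(prop, sig_a, alpha, alpha_lo, alpha_hi)
                  - hyper_lp(mu_a, sig_a, alpha, alpha_lo, alpha_hi);
        if (std::log(R::unif_rand()) < lr) { mu_a = prop; ad_mu_a.acc++; }
      }
    }
    {
      double prop = sig_a + R::norm_rand() * ad_sig_a.sd;
      ad_sig_a.tries++;
      if (prop >= sigma_alpha_prior[0] && prop <= sigma_alpha_prior[1] &&
          prop > 0) {
        double lr = hyper_lp(mu_a, prop, alpha, alpha_lo, alpha_hi)
                  - hyper_lp(mu_a, sig_a, alpha, alpha_lo, alpha_hi);
        if (std::log(R::unif_rand()) < lr) { sig_a = prop; ad_sig_a.acc++; }
      }
    }
    {
      double prop = mu_b + R::norm_rand() * ad_mu_b.sd;
      ad_mu_b.tries++;
      if (prop >= mu_beta_prior[0] && prop <= mu_beta_prior[1]) {
        double lr = hyper_lp(prop, sig_b, beta, beta_lo, beta_hi)
                  - hyper_lp(mu_b, sig_b, beta, beta_lo, beta_hi);
        if (std::log(R::unif_rand()) < lr) { mu_b = prop; ad_mu_b.acc++; }
      }
    }
    {
      double prop = sig_b + R::norm_rand() * ad_sig_b.sd;
      ad_sig_b.tries++;
      if (prop >= sigma_beta_prior[0] && prop <= sigma_beta_prior[1] &&
          prop > 0) {
        double lr = hyper_lp(mu_b, prop, beta, beta_lo, beta_hi)
                  - hyper_lp(mu_b, sig_b, beta, beta_lo, beta_hi);
        if (std::log(R::unif_rand()) < lr) { sig_b = prop; ad_sig_b.acc++; }
      }
    }

    // proposal adaptation, burn-in only (preserves detailed balance after)
    if (it <= burn_in && it % 50 == 0) {
      for (int i = 0; i < S; ++i) { ad_a[i].tune(); ad_b[i].tune(); }
      ad_mu_a.tune(); ad_sig_a.tune(); ad_mu_b.tune(); ad_sig_b.tune();
    }

    if (it > burn_in && (it - burn_in) % thin == 0 && keep < n_keep) {
      out(keep, 0) = mu_a; out(keep, 1) = sig_a;
      out(keep, 2) = mu_b; out(keep, 3) = sig_b;
      for (int i = 0; i < S; ++i) {
        out(keep, 4 + i) = alpha[i];
        out(keep, 4 + S + i) = beta[i];
      }
      ++keep;
    }
  }
  return out;
}
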