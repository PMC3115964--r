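// Gibbs-within-Metropolis sampler for the hierarchical Poisson-thinning
// model of Methyl-Seq region counts.
//
//   x_i ~ Poisson(lambda_i)                      (MspI)
//   y_i ~ Poisson(c * (1 - mu) * lambda_i)       (HpaII, thinned)
//   mu  ~ Uniform(0, 1)
//   poisson mode: lambda_i ~ Gamma(a0, b0)
//   negbin  mode: lambda_i ~ Gamma(r_i, eta_i), eta_i = (1 - p_i)/p_i,
//                 p_i ~ Uniform(0, 1), r_i ~ Gamma(r_shape, r_rate)
//
// Updates: lambda_i and phi = 1 - mu are conjugate Gibbs draws (phi is a
// Gamma(sum y + 1, c * sum lambda) truncated to (0,1), drawn by inverse
// CDF in log space). eta_i uses an independence Metropolis-Hastings step
// with proposal Gamma(r_i + 1, rate lambda_i), whose acceptance ratio is
// ((1 + eta)/(1 + eta'))^2 -- this mixes well for any r, unlike a random
// walk on logit p, whose conditional width shrinks as 1/sqrt(r). r_i uses
// a random walk on log r.
//
// All randomness comes from R's RNG, so set.seed() in R makes runs
// bit-reproducible.

#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

static inline double rtrunc_gamma01(double shape, double rate) {
  // draw from Gamma(shape, rate) truncated to (0, 1)
  double logF1 = R::pgamma(1.0, shape, 1.0 / rate, 1, 1);
  double u = R::runif(0.0, 1.0);
  double phi = R::qgamma(std::log(u) + logF1, shape, 1.0 / rate, 1, 1);
  if (!R_finite(phi) || phi <= 0.0) phi = DBL_MIN;
  if (phi >= 1.0) phi = 1.0 - 1e-12;
  return phi;
}

static inline double log_r_target(double lambda, double r, double eta,
                                  double r_shape, double r_rate) {
  // Gamma(lambda; r, rate eta) * Gamma(r; r_shape, r_rate), log scale
  return R::dgamma(lambda, r, 1.0 / eta, 1) +
         R::dgamma(r, r_shape, 1.0 / r_rate, 1);
}

// [[Rcpp::export]]
List mcmc_region_cpp(NumericVector x, NumericVector y, double cbias,
                     int mode, int n_chains, int burn_in, int n_samples,
                     double a0, double b0, double r_shape, double r_rate,
                     double fix_r, double rw_sd, NumericVector mu_init) {
  const int K = x.size();
  const int total = burn_in + n_samples;
  NumericMatrix mu_draws(n_samples, n_chains);
  NumericMatrix lambda_mean(K, n_chains);
  double acc_r = 0.0, acc_p = 0.0, try_r = 0.0, try_p = 0.0;

  double ysum = 0.0;
  for (int i = 0; i < K; ++i) ysum += y[i];

  for (int ch = 0; ch < n_chains; ++ch) {
    double mu = mu_init[ch];
    std::vector<double> lambda(K), r(K), eta(K, 1.0);
    for (int i = 0; i < K; ++i) {
      lambda[i] = x[i] > 1.0 ? x[i] : 1.0;
      r[i] = fix_r > 0.0 ? fix_r : 10.0;
    }

    for (int it = 0; it < total; ++it) {
      // lambda_i | rest  (conjugate)
      double lam_sum = 0.0;
      for (int i = 0; i < K; ++i) {
        double shape, rate;
        if (mode == 0) {
          shape = x[i] + y[i] + a0;
          rate = 1.0 + cbias * (1.0 - mu) + b0;
        } else {
          shape = x[i] + y[i] + r[i];
          rate = 1.0 + cbias * (1.0 - mu) + eta[i];
        }
        lambda[i] = R::rgamma(shape, 1.0 / rate);
        if (lambda[i] < 1e-300) lambda[i] = 1e-300;
        lam_sum += lambda[i];
      }

      if (mode == 1) {
        for (int i = 0; i < K; ++i) {
          // eta_i: independence MH, proposal Gamma(r_i + 1, rate lambda_i)
          double eta_prop = R::rgamma(r[i] + 1.0, 1.0 / lambda[i]);
          if (eta_prop > 1e-300) {
            double la = 2.0 * (std::log1p(eta[i]) - std::log1p(eta_prop));
            try_p += 1.0;
            if (std::log(R::runif(0.0, 1.0)) < la) {
              eta[i] = eta_prop;
              acc_p += 1.0;
            }
          }
          // r_i: random walk on log r
          if (fix_r <= 0.0) {
            double lr = std::log(r[i]);
            double lr_prop = lr + R::rnorm(0.0, rw_sd);
            double r_prop = std::exp(lr_prop);
            if (R_finite(r_prop) && r_prop > 1e-300) {
              double la = log_r_target(lambda[i], r_prop, eta[i],
                                       r_shape, r_rate) -
                          log_r_target(lambda[i], r[i], eta[i],
                                       r_shape, r_rate) +
                          lr_prop - lr;  // log-scale Jacobian
              try_r += 1.0;
              if (std::log(R::runif(0.0, 1.0)) < la) {
                r[i] = r_prop;
                acc_r += 1.0;
              }
            }
          }
        }
      }

      // phi = 1 - mu | rest: truncated Gamma(sum y + 1, c * sum lambda)
      double phi = rtrunc_gamma01(ysum + 1.0, cbias * lam_sum);
      mu = 1.0 - phi;

      if (it >= burn_in) {
        mu_draws(it - burn_in, ch) = mu;
        for (int i = 0; i < K; ++i) lambda_mean(i, ch) += lambda[i];
      }
    }
    for (int i = 0; i < K; ++i) lambda_mean(i, ch) /= n_samples;
  }

  return List::create(
    _["mu"] = mu_draws, _["lambda_mean"] = lambda_mean,
    _["accept_r"] = try_r > 0 ? acc_r / try_r : NA_REAL,
    _["accept_p"] = try_p > 0 ? acc_p / try_p : NA_REAL);
}
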