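# Independent numerical oracles used to validate the MCMC and the
# closed-form estimators. These deliberately avoid the package's own
# sampling code paths: everything here is deterministic quadrature /
# enumeration.

# Posterior density of mu for the Poisson-mode hierarchy, with lambda_i
# integrated out analytically:
#   p(mu | x, y) propto prod_i (c(1-mu))^{y_i} / (1 + c(1-mu) + b0)^{x_i+y_i+a0}
# on a fine midpoint grid over (0, 1). Returns the posterior mean of mu.
grid_posterior_mu <- function(x, y, cc = 1, a0 = 0.001, b0 = 0.001,
                              n_grid = 20001) {
  mu <- seq(1 / (2 * n_grid), 1 - 1 / (2 * n_grid), length.out = n_grid)
  phi <- cc * (1 - mu)
  loglik <- rep(0, n_grid)
  for (i in seq_along(x)) {
    term <- if (y[i] > 0) y[i] * log(phi) else 0
    loglik <- loglik + term - (x[i] + y[i] + a0) * log(1 + phi + b0)
  }
  w <- exp(loglik - max(loglik))
  sum(w * mu) / sum(w)
}

# Posterior mean of lambda for a single site at fixed mu, by quadrature of
# Poisson(x; lambda) * Poisson(y; c(1-mu)lambda) * Gamma prior. The
# integration runs on the log-lambda scale (substitution adds one power of
# lambda), which keeps the quadrature accurate down to the origin as long
# as the integrand is not power-law singular there, i.e. for
# x + y + prior_shape >= ~1.
grid_posterior_lambda_mean <- function(x, y, mu, cc = 1, a0 = 0.001,
                                       b0 = 0.001, n_grid = 30000) {
  upper <- max(8 * (x + y + 1), 80)
  u <- seq(log(1e-10), log(upper), length.out = n_grid)
  lam <- exp(u)
  logw <- dpois(x, lam, log = TRUE) +
    dgamma(lam, shape = a0, rate = b0, log = TRUE) +
    dpois(y, cc * (1 - mu) * lam, log = TRUE) +
    u  # Jacobian of lambda = exp(u)
  w <- exp(logw - max(logw))
  sum(w * lam) / sum(w)
}

# CDF of Gamma(shape, rate) truncated to (0, 1), for Kolmogorov tests.
trunc_gamma_cdf <- function(q, shape, rate) {
  pgamma(pmin(q, 1), shape, rate = rate) / pgamma(1, shape, rate = rate)
}

# Monte-Carlo standard error of the posterior-mean estimate from parallel
# chains: the spread of per-chain means honestly reflects autocorrelation.
mc_se <- function(mu_chains) {
  m <- colMeans(mu_chains)
  sd(m) / sqrt(length(m))
}

# Brute-force AUC: average over all (positive, negative) pairs, ties 1/2.
pairwise_auc <- function(predictor, labels) {
  pos <- predictor[labels]
  neg <- predictor[!labels]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Direct transcription of the Williams t formula, kept separate from the
# package implementation.
williams_t_direct <- function(r1, r2, r12, n) {
  detR <- 1 - r1^2 - r2^2 - r12^2 + 2 * r1 * r2 * r12
  rbar <- (r1 + r2) / 2
  (r1 - r2) * sqrt((n - 1) * (1 + r12) /
    (2 * ((n - 1) / (n - 3)) * detR + rbar^2 * (1 - r12)^3))
}
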