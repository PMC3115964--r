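test_that("lambda full conditional matches the conjugate algebra", {
  expect_equal(conditional_lambda_params(10, 0, mu = 1, c = 1, 0.001, 0.001),
               c(shape = 10.001, rate = 1.001))
  expect_equal(conditional_lambda_params(5, 5, mu = 0, c = 1, 0.001, 0.001),
               c(shape = 10.001, rate = 2.001))
  expect_error(conditional_lambda_params(5, 5, mu = 1.2), "\\[0, 1\\]")
  expect_error(conditional_lambda_params(-1, 5, mu = 0.5), "non-negative")
})

test_that("conjugate posterior mean agrees with grid quadrature over all small counts", {
  # full sweep with a smooth Gamma(2, 1) prior: quadrature is reliable for
  # every x, y including (0, 0), and the conjugate algebra is the same
  mu <- 0.37
  for (x in 0:20) {
    for (y in 0:20) {
      p <- conditional_lambda_params(x, y, mu, prior_shape = 2,
                                     prior_rate = 1)
      oracle <- grid_posterior_lambda_mean(x, y, mu, a0 = 2, b0 = 1)
      expect_equal(unname(p["shape"] / p["rate"]), oracle, tolerance = 1e-3)
    }
  }
  # vague default prior, bias ratio, and mu extremes enter the rate
  # correctly (x + y >= 1 keeps the reference quadrature non-singular)
  for (case in list(c(8, 3, 0, 0.5), c(8, 0, 1, 2), c(0, 6, 0.2, 1),
                    c(12, 7, 0.8, 1.5))) {
    p <- conditional_lambda_params(case[1], case[2], case[3], case[4])
    oracle <- grid_posterior_lambda_mean(case[1], case[2], case[3], case[4])
    expect_equal(unname(p["shape"] / p["rate"]), oracle, tolerance = 1e-3)
  }
})

test_that("phi sampler draws from the truncated Gamma", {
  ks <- function(draws, cdf) {
    s <- sort(draws)
    n <- length(s)
    max(abs(cdf(s) - seq_len(n) / n), abs(cdf(s) - (seq_len(n) - 1) / n))
  }
  set.seed(5)
  # flat-likelihood limit: Uniform(0,1)
  d <- sample_phi(0, 1e-8, n = 1e5)
  expect_lt(ks(d, function(q) q), 0.01)
  # generic case vs quadrature CDF
  d <- sample_phi(5, 10, n = 1e5)
  expect_true(all(d > 0 & d < 1))
  expect_lt(ks(d, function(q) trunc_gamma_cdf(q, 6, 10)), 0.01)
  # negligible-truncation case: untruncated Gamma mean 51/100
  d <- sample_phi(50, 100, n = 1e5)
  expect_lt(abs(mean(d) - 0.51), 3 * sd(d) / sqrt(length(d)))
  expect_error(sample_phi(-1, 5), ">= 0")
  expect_error(sample_phi(5, Inf), "finite")
})

test_that("Poisson-mode posterior means match deterministic grid integration", {
  cases <- list(list(x = c(50, 50), y = c(0, 0)),
                list(x = 100, y = 50),
                list(x = c(3, 0, 7), y = c(1, 0, 2)),
                list(x = 20, y = 18),
                list(x = c(5, 5), y = c(10, 8)))
  # many medium chains: the between-chain spread then estimates the
  # Monte-Carlo error reliably (15 df) despite within-chain autocorrelation
  cfg <- bayes_config(mode = "poisson", n_chains = 16, burn_in = 1000,
                      n_samples = 2000)
  for (i in seq_along(cases)) {
    cfg$seed <- 900 + i
    fit <- fit_bayes_region(cases[[i]]$x, cases[[i]]$y, config = cfg)
    oracle <- grid_posterior_mu(cases[[i]]$x, cases[[i]]$y)
    expect_lt(abs(fit$mu_mean - oracle), 3 * mc_se(fit$mu_chains))
    expect_gt(fit$mu_mean, 0); expect_lt(fit$mu_mean, 1)
    expect_gt(fit$mu_variance, 0)
  }
  # fully methylated region: posterior mass near 1
  cfg$seed <- 77
  expect_gt(fit_bayes_region(c(50, 50), c(0, 0), config = cfg)$mu_mean, 0.9)
})

test_that("posterior stays strictly inside (0,1) where TPE truncates", {
  cfg <- bayes_config(seed = 13)
  fit <- fit_bayes_region(5, 50, config = cfg)  # HpaII 10x MspI
  expect_equal(tpe(5, 50), 0)
  expect_gt(fit$mu_mean, 0)
  expect_lt(fit$mu_mean, 1)
  fit1 <- fit_bayes_region(50, 0, config = cfg)  # no HpaII signal
  expect_equal(tpe(50, 0), 1)
  expect_lt(fit1$mu_mean, 1)
})

test_that("depth-bias ratio moves the posterior in the correcting direction", {
  f1 <- fit_bayes_region(10, 10, c = 1, config = bayes_config(seed = 3))
  f2 <- fit_bayes_region(10, 10, c = 2, config = bayes_config(seed = 3))
  expect_gt(f2$mu_mean, f1$mu_mean)
})

test_that("fixed seed reproduces the fit bit-exactly", {
  cfg <- bayes_config(seed = 123)
  f1 <- fit_bayes_region(c(12, 30), c(4, 9), config = cfg)
  f2 <- fit_bayes_region(c(12, 30), c(4, 9), config = cfg)
  expect_identical(f1$mu_samples, f2$mu_samples)
  expect_identical(f1$lambda_means, f2$lambda_means)
  expect_identical(f1$mu_mean, f2$mu_mean)
})

test_that("degenerate regions are rejected", {
  expect_error(fit_bayes_region(c(0, 0), c(0, 0)), "no information")
  expect_error(fit_bayes_region(integer(0), integer(0)), "non-empty")
  expect_error(fit_bayes_region(5, 5, c = -1), "positive")
})

test_that("negbin mode with large fixed r reproduces the Poisson posterior", {
  # NB(r, p) -> Poisson as r -> Inf; with p ~ U(0,1) and r fixed large the
  # induced prior on lambda = r p/(1-p) is locally flat, so the matching
  # Poisson-mode run uses a flat Gamma(1, ~0) prior. Chains are long
  # because the (lambda, p) pair mixes at rate ~ (x+y)/r.
  x <- c(12, 8); y <- c(5, 3)
  cfg_nb <- bayes_config(mode = "negbin", fix_r = 2000, n_chains = 6,
                         burn_in = 3000, n_samples = 3000, seed = 41)
  cfg_po <- bayes_config(mode = "poisson", lambda_prior_shape = 1,
                         lambda_prior_rate = 1e-9, n_chains = 6,
                         burn_in = 1000, n_samples = 3000, seed = 42)
  f_nb <- fit_bayes_region(x, y, config = cfg_nb)
  f_po <- fit_bayes_region(x, y, config = cfg_po)
  tol <- 3 * sqrt(mc_se(f_nb$mu_chains)^2 + mc_se(f_po$mu_chains)^2)
  expect_lt(abs(f_nb$mu_mean - f_po$mu_mean), tol)
})

test_that("negbin mode reports the full parameter count and mixes", {
  fit <- fit_bayes_region(c(40, 60, 55), c(20, 22, 30),
                          config = bayes_config(seed = 9))
  expect_equal(fit$n_params, 3 * 3 + 1)
  expect_gt(fit$accept_p, 0.2)  # independence MH should accept freely
  expect_lt(fit$rhat, 1.1)
  fitp <- fit_bayes_region(c(40, 60), c(20, 22),
                           config = bayes_config(mode = "poisson", seed = 9))
  expect_equal(fitp$n_params, 3)
})

test_that("Gelman-Rubin statistic behaves and matches a direct recomputation", {
  set.seed(6)
  base <- rnorm(1000)
  expect_equal(gelman_rubin(cbind(base, base)), 1, tolerance = 1e-3)
  far <- cbind(rnorm(500, 0, 0.01), rnorm(500, 10, 0.01))
  expect_gt(gelman_rubin(far), 10)
  chains <- matrix(rnorm(3000), 1000, 3)
  n <- nrow(chains); m <- ncol(chains)
  W <- mean(apply(chains, 2, var))
  B <- n / (m - 1) * sum((colMeans(chains) - mean(chains))^2)
  direct <- sqrt(((n - 1) / n * W + B / n) / W)
  expect_equal(gelman_rubin(chains), direct, tolerance = 1e-10)
  expect_error(gelman_rubin(matrix(1:10, ncol = 1)), "2 chains")
})
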