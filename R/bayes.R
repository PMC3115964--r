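#' MCMC configuration for the hierarchical count model
#'
#' The model treats the MspI tag count of site i as Poisson with a
#' site-specific depth `lambda_i`, and the HpaII count of the same site as
#' a Poisson thinning of that depth: `y_i ~ Poisson(c * (1 - mu) * lambda_i)`,
#' where `mu` is the region methylation level shared by all K sites and
#' `c` the library-wide depth-bias ratio. In `negbin` mode the depth gets
#' an extra Gamma layer, `lambda_i ~ Gamma(r_i, rate (1 - p_i)/p_i)`
#' (so marginally the MspI count is negative binomial NB(r_i, p_i) and
#' `r_i -> Inf` recovers the Poisson mode), with `p_i ~ Uniform(0,1)` and
#' `r_i ~ Gamma(r_prior_shape, r_prior_rate)`. In `poisson` mode
#' `lambda_i ~ Gamma(lambda_prior_shape, lambda_prior_rate)` (vague by
#' default). `mu` always carries a Uniform(0,1) prior.
#'
#' @param mode `"negbin"` (default, Gamma-Poisson mixture) or `"poisson"`.
#' @param n_chains number of independent chains (>= 2; default 3).
#' @param burn_in iterations discarded per chain (default 500).
#' @param n_samples retained iterations per chain (default 500).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param lambda_prior_shape,lambda_prior_rate vague Gamma hyperprior on
#'   `lambda_i` in poisson mode (default 0.001, 0.001).
#' @param r_prior_shape,r_prior_rate vague Gamma hyperprior on `r_i`
#'   (default 0.01, 0.01).
#' @param fix_r fix the over-dispersion parameter at this value instead of
#'   sampling it (negbin mode only); `NULL` to sample.
#' @param rw_sd random-walk standard deviation for the log-`r` Metropolis
#'   update.
#' @param rhat_threshold flag fits whose potential scale reduction exceeds
#'   this (default 1.1); convergence is reported, not enforced.
#' @return a `bayes_config` list.
#' @export
bayes_config <- function(mode = c("negbin", "poisson"), n_chains = 3,
                         burn_in = 500, n_samples = 500, seed = NULL,
                         lambda_prior_shape = 0.001,
                         lambda_prior_rate = 0.001,
                         r_prior_shape = 0.01, r_prior_rate = 0.01,
                         fix_r = NULL, rw_sd = 0.8,
                         rhat_threshold = 1.1) {
  mode <- match.arg(mode)
  stopifnot(n_chains >= 2, burn_in >= 1, n_samples >= 1,
            lambda_prior_shape > 0, lambda_prior_rate > 0,
            r_prior_shape > 0, r_prior_rate > 0, rw_sd > 0,
            is.null(fix_r) || fix_r > 0)
  out <- list(mode = mode, n_chains = as.integer(n_chains),
              burn_in = as.integer(burn_in),
              n_samples = as.integer(n_samples), seed = NULL,
              lambda_prior_shape = lambda_prior_shape,
                 lambda_prior_rate = lambda_prior_rate,
                 r_prior_shape = r_prior_shape,
                 r_prior_rate = r_prior_rate,
              fix_r = if (is.null(fix_r)) -1 else fix_r,
              rw_sd = rw_sd, rhat_threshold = rhat_threshold)
  out["seed"] <- list(if (is.null(seed)) NULL else as.integer(seed))
  structure(out, class = "bayes_config")
}

#' Gamma full-conditional of a site depth parameter
#'
#' Conjugate update for `lambda_i` given the data and current `mu`:
#' both the MspI count (rate `lambda_i`) and the thinned HpaII count
#' (rate `c (1 - mu) lambda_i`) are Poisson in `lambda_i`, and the Gamma
#' prior (in negbin mode, the Gamma mixing distribution implied by
#' `(r_i, p_i)`) is conjugate.
#'
#' @param x_i,y_i MspI and HpaII counts at the site.
#' @param mu current methylation level in \[0, 1\].
#' @param c depth-bias ratio.
#' @param prior_shape,prior_rate Gamma prior parameters (`r_i` and
#'   `(1 - p_i)/p_i` in negbin mode).
#' @return named vector `c(shape, rate)`: shape `x_i + y_i + prior_shape`,
#'   rate `1 + c (1 - mu) + prior_rate`.
#' @examples
#' conditional_lambda_params(10, 0, mu = 1, c = 1, 0.001, 0.001)
#' @export
conditional_lambda_params <- function(x_i, y_i, mu, c = 1,
                                      prior_shape = 0.001,
                                      prior_rate = 0.001) {
  .check_counts(x_i, "x_i"); .check_counts(y_i, "y_i")
  if (!is.finite(mu) || mu < 0 || mu > 1) stop("`mu` must be in [0, 1]")
  stopifnot(c > 0, prior_shape > 0, prior_rate > 0)
  c(shape = x_i + y_i + prior_shape,
    rate = 1 + c * (1 - mu) + prior_rate)
}

#' Sample the unmethylated fraction from its full conditional
#'
#' Under the Uniform(0,1) prior on `mu`, the full conditional of
#' `phi = 1 - mu` given the HpaII counts and current depths is
#' `Gamma(sum(y) + 1, rate = c * sum(lambda))` truncated to (0, 1). Draws
#' use the inverse CDF in log space, which stays accurate when the
#' truncation retains little or nearly all of the Gamma mass.
#'
#' @param y_sum total HpaII count of the region (>= 0).
#' @param lambda_eff_sum `c * sum(lambda_i)`, the effective thinning rate
#'   total (> 0).
#' @param n number of draws.
#' @return `n` draws of `phi` strictly inside (0, 1); the methylation
#'   level is `1 - phi`.
#' @export
sample_phi <- function(y_sum, lambda_eff_sum, n = 1) {
  if (!is.finite(y_sum) || !is.finite(lambda_eff_sum) ||
      y_sum < 0 || lambda_eff_sum <= 0) {
    stop("`y_sum` must be >= 0 and `lambda_eff_sum` > 0 and finite")
  }
  shape <- y_sum + 1
  logF1 <- pgamma(1, shape, rate = lambda_eff_sum, log.p = TRUE)
  u <- runif(n)
  phi <- qgamma(log(u) + logF1, shape, rate = lambda_eff_sum, log.p = TRUE)
  pmin(pmax(phi, .Machine$double.xmin), 1 - 1e-12)
}

#' Fit the Bayesian hierarchical model to one region
#'
#' Runs `n_chains` independent Gibbs-within-Metropolis chains
#' (conjugate Gibbs updates for the site depths `lambda_i` and the
#' unmethylated fraction `phi = 1 - mu`; in negbin mode,
#' independence-Metropolis updates for the Gamma-mixture rate implied by
#' `p_i` and random-walk Metropolis on `log r_i`), discards the burn-in,
#' pools the post-burn-in draws, and summarizes the posterior of `mu`.
#' Chains start from deterministically staggered `mu` values so a fixed
#' seed reproduces the fit bit-exactly.
#'
#' @param x MspI collapsed counts (length K >= 1).
#' @param y HpaII collapsed counts for one library (length K).
#' @param c depth-bias ratio (HpaII/MspI), default 1.
#' @param config a [bayes_config()].
#' @return an object of class `posterior_summary`: `mu_mean` (posterior
#'   mean, strictly in (0,1)), `mu_variance` (> 0), `mu_samples` (pooled
#'   draws), `mu_chains` (draws per chain), `lambda_means`, `rhat`,
#'   `converged`, `n_params` (`3K + 1` in negbin mode, `K + 1` in poisson
#'   mode), `accept_r`/`accept_p` Metropolis acceptance rates.
#' @examples
#' fit <- fit_bayes_region(c(50, 50), c(25, 20),
#'                         config = bayes_config(seed = 1))
#' fit$mu_mean
#' @export
fit_bayes_region <- function(x, y, c = 1, config = bayes_config()) {
  if (length(x) != length(y) || length(x) < 1) {
    stop("`x` and `y` must be non-empty and of equal length")
  }
  .check_counts(x, "x"); .check_counts(y, "y")
  if (!is.finite(c) || c <= 0) stop("`c` must be a positive finite number")
  if (sum(x) == 0 && sum(y) == 0) {
    stop("no information: all MspI and HpaII counts are zero")
  }
  if (!inherits(config, "bayes_config")) stop("`config` must be a bayes_config")
  if (!is.null(config$seed)) set.seed(config$seed)
  K <- length(x)
  mu_init <- seq_len(config$n_chains) / (config$n_chains + 1)
  res <- mcmc_region_cpp(as.numeric(x), as.numeric(y), c,
                         mode = if (config$mode == "poisson") 0L else 1L,
                         n_chains = config$n_chains,
                         burn_in = config$burn_in,
                         n_samples = config$n_samples,
                         a0 = config$lambda_prior_shape,
                         b0 = config$lambda_prior_rate,
                         r_shape = config$r_prior_shape,
                         r_rate = config$r_prior_rate,
                         fix_r = config$fix_r, rw_sd = config$rw_sd,
                         mu_init = mu_init)
  mu_chains <- res$mu
  draws <- as.vector(mu_chains)
  rhat <- gelman_rubin(mu_chains)
  out <- list(mu_mean = mean(draws), mu_variance = var(draws),
              mu_samples = draws, mu_chains = mu_chains,
              lambda_means = rowMeans(res$lambda_mean),
              rhat = rhat, converged = rhat <= config$rhat_threshold,
              n_params = if (config$mode == "poisson") K + 1L else 3L * K + 1L,
              mode = config$mode,
              accept_r = res$accept_r, accept_p = res$accept_p)
  class(out) <- "posterior_summary"
  if (!out$converged) {
    warning(sprintf("R-hat %.3f exceeds threshold %.2f; consider more iterations",
                    rhat, config$rhat_threshold))
  }
  out
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf(
    "<posterior_summary> mu = %.4f (sd %.4f), rhat = %.3f, %s mode, %d params\n",
    x$mu_mean, sqrt(x$mu_variance), x$rhat, x$mode, x$n_params))
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Split-free R-hat over parallel chains: with m chains of n draws,
#' between-chain variance B, within-chain variance W, the statistic is
#' `sqrt(((n - 1)/n * W + B/n) / W)`.
#'
#' @param chains an n x m matrix (draws by chains) or list of equal-length
#'   numeric vectors.
#' @return R-hat; ~1 for well-mixed chains, >> 1 for disagreeing chains.
#' @export
gelman_rubin <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  chains <- as.matrix(chains)
  m <- ncol(chains); n <- nrow(chains)
  if (m < 2) stop("at least 2 chains are required")
  if (n < 2) stop("at least 2 draws per chain are required")
  means <- colMeans(chains)
  W <- mean(apply(chains, 2, var))
  B <- n * var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}
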