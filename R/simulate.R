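#' Methylation-level distributions for simulation
#'
#' Generators draw one true methylation level per (region, library) from a
#' `mu_distribution`. Genome-wide methylation is strongly bimodal (most
#' regions nearly fully methylated or nearly unmethylated), so the default
#' is a U-shaped `Beta(0.4, 0.4)` standing in for the empirical microarray
#' beta-value density. `mu_fixed()` pins the level (for variance studies)
#' and `mu_table()` resamples an empirical table of levels.
#'
#' @param alpha,beta positive Beta shape parameters.
#' @param value fixed level in \[0, 1\].
#' @param values numeric vector of empirical levels in \[0, 1\].
#' @return a `mu_distribution` object.
#' @export
mu_beta <- function(alpha = 0.4, beta = 0.4) {
  stopifnot(alpha > 0, beta > 0)
  structure(list(kind = "bimodal_beta", alpha = alpha, beta = beta),
            class = "mu_distribution")
}

#' @rdname mu_beta
#' @export
mu_fixed <- function(value) {
  stopifnot(is.finite(value), value >= 0, value <= 1)
  structure(list(kind = "fixed", value = value), class = "mu_distribution")
}

#' @rdname mu_beta
#' @export
mu_table <- function(values) {
  stopifnot(length(values) > 0, all(values >= 0), all(values <= 1))
  structure(list(kind = "empirical_table", values = values),
            class = "mu_distribution")
}

sample_mu <- function(dist, n) {
  stopifnot(inherits(dist, "mu_distribution"))
  switch(dist$kind,
         bimodal_beta = rbeta(n, dist$alpha, dist$beta),
         fixed = rep(dist$value, n),
         empirical_table = sample(dist$values, n, replace = TRUE))
}

#' Empirical distribution of region sizes
#'
#' Genome-wide, 77% of the ~90,000 Methyl-Seq regions contain exactly two
#' cleavage sites and 95% contain at most five. The default categorical
#' distribution reproduces those quantiles: P(K=2) = 0.77, K in 3..5
#' sharing 0.18 uniformly, K in 6..10 sharing 0.05 uniformly.
#'
#' @return named numeric vector of probabilities (names are K values).
#' @export
region_size_probs <- function() {
  p <- c(0.77, rep(0.18 / 3, 3), rep(0.05 / 5, 5))
  names(p) <- as.character(2:10)
  p
}

#' Draw region sizes K
#'
#' @param n_regions number of regions.
#' @param size_probs named probability vector (names = K values); default
#'   [region_size_probs()].
#' @return integer vector of K >= 1.
#' @export
sample_region_sizes <- function(n_regions, size_probs = region_size_probs()) {
  stopifnot(n_regions >= 1, all(size_probs >= 0), sum(size_probs) > 0)
  ks <- as.integer(names(size_probs))
  ks[sample.int(length(ks), n_regions, replace = TRUE, prob = size_probs)]
}

## shared structure draw: sizes, then the truth matrix (regions x libraries)
.sim_structure <- function(n_regions, n_libraries, mu_dist, size_probs) {
  K <- sample_region_sizes(n_regions, size_probs)
  mu <- matrix(sample_mu(mu_dist, n_regions * n_libraries),
               nrow = n_regions, ncol = n_libraries)
  libs <- sprintf("lib%d", seq_len(n_libraries))
  list(K = K, mu = mu, libs = libs,
       region_ids = sprintf("r%04d", seq_len(n_regions)))
}

## count draw given structure. depth_h: n_regions x n_libraries matrix of
## HpaII depths (before bias); cvec: per-library bias multipliers;
## x_fixed: NULL (Poisson MspI counts) or a constant MspI count.
.sim_counts <- function(st, depth_mspi, depth_h, cvec, thinning,
                        x_fixed = NULL) {
  n_regions <- length(st$K)
  regions <- vector("list", n_regions)
  for (g in seq_len(n_regions)) {
    k <- st$K[g]
    pos <- 10000L * g + 40L * (seq_len(k) - 1L)
    x <- if (is.null(x_fixed)) rpois(k, depth_mspi) else rep(x_fixed, k)
    yl <- matrix(0L, k, length(st$libs), dimnames = list(NULL, st$libs))
    for (j in seq_along(st$libs)) {
      rate1 <- cvec[j] * depth_h[g, j]
      if (thinning == "marginal") {
        yl[, j] <- rpois(k, (1 - st$mu[g, j]) * rate1)
      } else {
        n_star <- rpois(k, rate1)
        yl[, j] <- rbinom(k, n_star, 1 - st$mu[g, j])
      }
    }
    sites <- data.frame(site_id = sprintf("s%d", seq_len(k)), pos = pos,
                        mspi_fwd = x, mspi_rev = 0L, mspi = x,
                        stringsAsFactors = FALSE)
    regions[[g]] <- new_region(st$region_ids[g], "chrSim", sites,
                               hpaii = yl, hpaii_fwd = yl,
                               hpaii_rev = matrix(0L, k, length(st$libs),
                                                  dimnames = list(NULL, st$libs)))
  }
  regions
}

.sim_truth <- function(st) {
  data.frame(region_id = rep(st$region_ids, times = length(st$libs)),
             library_id = rep(st$libs, each = length(st$K)),
             mu = as.vector(st$mu), stringsAsFactors = FALSE)
}

#' Simulate a Methyl-Seq tag-count dataset
#'
#' Per site, the MspI count is Poisson with mean `depth`; per library, the
#' HpaII count is Poisson with mean `c_j * (1 - mu) * depth`, where `mu`
#' is the true level of the (region, library) pair drawn from `mu_dist`.
#' Region sizes follow [region_size_probs()]. The default sizes mirror
#' the benchmark design: 6 libraries x 155 regions = 930 levels.
#'
#' @param n_regions,n_libraries dataset dimensions.
#' @param depth expected tag count per cleavage site (both libraries).
#' @param mu_dist a [mu_beta()]-style distribution of true levels.
#' @param bias optional per-library depth-bias multipliers `c_j` (named or
#'   positional); default none (all 1).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param thinning `"marginal"` draws HpaII counts from their Poisson
#'   marginal; `"binomial"` thins an independent Poisson count
#'   tag-by-tag (identical marginal law).
#' @param size_probs region-size distribution override.
#' @return a `methylseq_dataset`: `regions` (list of `methyl_region`),
#'   `truth` (region_id, library_id, mu), `params`.
#' @export
simulate_methylseq <- function(n_regions = 155, n_libraries = 6, depth = 50,
                               mu_dist = mu_beta(), bias = NULL, seed = NULL,
                               thinning = c("marginal", "binomial"),
                               size_probs = region_size_probs()) {
  thinning <- match.arg(thinning)
  stopifnot(depth > 0)
  if (!is.null(seed)) set.seed(seed)
  st <- .sim_structure(n_regions, n_libraries, mu_dist, size_probs)
  cvec <- rep(1, n_libraries)
  if (!is.null(bias)) cvec[seq_along(bias)] <- bias
  depth_h <- matrix(depth, n_regions, n_libraries)
  regions <- .sim_counts(st, depth, depth_h, cvec, thinning)
  structure(list(regions = regions, truth = .sim_truth(st),
                 params = list(design = "methylseq", n_regions = n_regions,
                               n_libraries = n_libraries, depth = depth,
                               mu_dist = unclass(mu_dist), bias = bias,
                               thinning = thinning, size_probs = size_probs,
                               seed = seed)),
            class = "methylseq_dataset")
}

#' @export
print.methylseq_dataset <- function(x, ...) {
  cat(sprintf("<methylseq_dataset> %d regions x %d libraries (%d levels)\n",
              length(x$regions), length(unique(x$truth$library_id)),
              nrow(x$truth)))
  invisible(x)
}

#' Simulate Methyl-Seq with discordant MspI/HpaII sequencing depths
#'
#' The MspI depth is the constant `depth_mspi`; each region receives its
#' own local HpaII depth drawn log-normally around it:
#' `log(depth_hpaii) ~ Normal(log(depth_mspi), sigma^2)` (shared by the
#' region's libraries — the discordance is a regional property of the
#' HpaII digestion), so the median HpaII depth equals the MspI depth and
#' `sigma` controls the discordance. `sigma = 0` reduces bit-exactly to
#' [simulate_methylseq()] under the same seed.
#'
#' @param depth_mspi MspI sequencing depth per site (> 0).
#' @param sigma log-scale depth-discordance standard deviation (>= 0).
#' @param n_datasets number of independent datasets (dataset d uses seed
#'   `seed + d - 1`).
#' @inheritParams simulate_methylseq
#' @return list of `methylseq_dataset` objects (length `n_datasets`).
#' @export
simulate_discordant <- function(depth_mspi, sigma, n_datasets = 1,
                                n_regions = 155, n_libraries = 6,
                                mu_dist = mu_beta(), seed = NULL,
                                size_probs = region_size_probs()) {
  stopifnot(depth_mspi > 0, sigma >= 0, n_datasets >= 1)
  lapply(seq_len(n_datasets), function(d) {
    if (!is.null(seed)) set.seed(seed + d - 1)
    st <- .sim_structure(n_regions, n_libraries, mu_dist, size_probs)
    depth_h <- if (sigma > 0) {
      matrix(depth_mspi * exp(rnorm(n_regions, 0, sigma)),
             n_regions, n_libraries)
    } else {
      matrix(depth_mspi, n_regions, n_libraries)
    }
    regions <- .sim_counts(st, depth_mspi, depth_h, rep(1, n_libraries),
                           "marginal")
    structure(list(regions = regions, truth = .sim_truth(st),
                   params = list(design = "discordance",
                                 depth_mspi = depth_mspi, sigma = sigma,
                                 depth_hpaii = depth_h[, 1],
                                 dataset_index = d, n_regions = n_regions,
                                 n_libraries = n_libraries,
                                 mu_dist = unclass(mu_dist),
                                 size_probs = size_probs,
                                 seed = if (is.null(seed)) NULL else seed + d - 1)),
              class = "methylseq_dataset")
  })
}

#' Simulate a pair of technical replicates
#'
#' Draws one truth table (region sizes and true levels), then two
#' independent count tables from it — repeated sequencing of the same
#' biological sample. Used to measure quantification consistency as a
#' function of depth.
#'
#' @inheritParams simulate_methylseq
#' @return list with elements `rep1` and `rep2`, two `methylseq_dataset`s
#'   sharing an identical `truth`.
#' @export
simulate_replicates <- function(depth, n_regions = 155, n_libraries = 6,
                                mu_dist = mu_beta(), seed = NULL,
                                size_probs = region_size_probs()) {
  stopifnot(depth > 0)
  if (!is.null(seed)) set.seed(seed)
  st <- .sim_structure(n_regions, n_libraries, mu_dist, size_probs)
  depth_h <- matrix(depth, n_regions, n_libraries)
  cvec <- rep(1, n_libraries)
  mk <- function(idx) {
    regions <- .sim_counts(st, depth, depth_h, cvec, "marginal")
    structure(list(regions = regions, truth = .sim_truth(st),
                   params = list(design = "replicates", replicate = idx,
                                 depth = depth, n_regions = n_regions,
                                 n_libraries = n_libraries,
                                 mu_dist = unclass(mu_dist),
                                 size_probs = size_probs, seed = seed)),
              class = "methylseq_dataset")
  }
  list(rep1 = mk(1L), rep2 = mk(2L))
}

## Gauss-Hermite nodes/weights (probabilists' convention) via Golub-Welsch
.gauss_hermite_prob <- function(n) {
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(z = sqrt(2) * e$values, w = e$vectors[1, ]^2)
}

## Pearson correlation of (g(Z1), g(Z2)) under a Gaussian copula with
## latent correlation rho_lat, g = qbeta(pnorm(.), alpha, beta)
.copula_pearson <- function(rho_lat, alpha, beta, gh = .gauss_hermite_prob(80)) {
  g <- qbeta(pnorm(gh$z), alpha, beta)
  m <- sum(gh$w * g)
  v <- sum(gh$w * g^2) - m^2
  s <- sqrt(max(1 - rho_lat^2, 0))
  inner <- vapply(gh$z, function(z1) {
    sum(gh$w * qbeta(pnorm(rho_lat * z1 + s * gh$z), alpha, beta))
  }, numeric(1))
  egg <- sum(gh$w * g * inner)
  (egg - m^2) / v
}

## latent correlation achieving a target Pearson correlation of the betas
.calibrate_copula <- function(rho, alpha, beta) {
  if (rho >= 1) return(1)
  if (rho <= 0) return(0)
  gh <- .gauss_hermite_prob(80)
  uniroot(function(rl) .copula_pearson(rl, alpha, beta, gh) - rho,
          interval = c(0, 1 - 1e-9), tol = 1e-9)$root
}

#' Simulate two-site regions with correlated methylation levels
#'
#' Site pairs receive true levels `(mu1, mu2)` with identical Beta
#' marginals and a target Pearson correlation `rho`, generated through a
#' Gaussian copula whose latent correlation is calibrated by quadrature
#' so the *output* correlation matches `rho`. MspI counts are fixed at the
#' design depth (`x = round(depth)`); HpaII counts are Poisson with mean
#' `(1 - mu_i) * depth`. One library. Used to compare site-level against
#' region-level quantification.
#'
#' @param rho target Pearson correlation between neighboring site levels,
#'   in \[0, 1\] (`rho = 1` makes the pair identical).
#' @param depth sequencing depth (MspI counts fixed at `round(depth)`).
#' @param n_sites total number of sites (must be even; `n_sites/2`
#'   two-site regions).
#' @param mu_marginal marginal level distribution; must be [mu_beta()].
#' @param seed integer seed.
#' @return a `methylseq_dataset` whose `truth` holds the per-region mean
#'   level and `truth_sites` the per-site levels.
#' @export
simulate_correlated_sites <- function(rho, depth, n_sites = 2000,
                                      mu_marginal = mu_beta(), seed = NULL) {
  if (!is.finite(rho) || rho < 0 || rho > 1) stop("`rho` must be in [0, 1]")
  stopifnot(depth > 0, n_sites >= 2, n_sites %% 2 == 0)
  if (mu_marginal$kind != "bimodal_beta") {
    stop("correlated-site simulation requires a bimodal_beta marginal")
  }
  if (!is.null(seed)) set.seed(seed)
  n_regions <- n_sites %/% 2
  rho_lat <- .calibrate_copula(rho, mu_marginal$alpha, mu_marginal$beta)
  z1 <- rnorm(n_regions)
  z2 <- if (rho >= 1) z1 else rho_lat * z1 + sqrt(1 - rho_lat^2) * rnorm(n_regions)
  mu1 <- qbeta(pnorm(z1), mu_marginal$alpha, mu_marginal$beta)
  mu2 <- qbeta(pnorm(z2), mu_marginal$alpha, mu_marginal$beta)

  x_fixed <- as.integer(round(depth))
  region_ids <- sprintf("r%04d", seq_len(n_regions))
  regions <- vector("list", n_regions)
  truth_sites <- vector("list", n_regions)
  for (g in seq_len(n_regions)) {
    mus <- c(mu1[g], mu2[g])
    y <- rpois(2, (1 - mus) * depth)
    sites <- data.frame(site_id = c("s1", "s2"),
                        pos = 10000L * g + c(0L, 40L),
                        mspi_fwd = x_fixed, mspi_rev = 0L, mspi = x_fixed,
                        stringsAsFactors = FALSE)
    regions[[g]] <- new_region(region_ids[g], "chrSim", sites,
                               hpaii = matrix(y, 2, 1,
                                              dimnames = list(NULL, "lib1")),
                               hpaii_fwd = matrix(y, 2, 1,
                                                  dimnames = list(NULL, "lib1")),
                               hpaii_rev = matrix(0L, 2, 1,
                                                  dimnames = list(NULL, "lib1")))
    truth_sites[[g]] <- data.frame(region_id = region_ids[g],
                                   site_id = c("s1", "s2"),
                                   library_id = "lib1", mu = mus,
                                   stringsAsFactors = FALSE)
  }
  truth <- data.frame(region_id = region_ids, library_id = "lib1",
                      mu = (mu1 + mu2) / 2, stringsAsFactors = FALSE)
  structure(list(regions = regions, truth = truth,
                 truth_sites = do.call(rbind, truth_sites),
                 params = list(design = "correlated", rho = rho,
                               rho_latent = rho_lat, depth = depth,
                               n_sites = n_sites,
                               mu_dist = unclass(mu_marginal), seed = seed)),
            class = "methylseq_dataset")
}

#' Simulate an RRBS dataset
#'
#' Bisulfite flavor of the benchmark: per site, the methylated-read count
#' is Poisson with mean `mu * depth` and the unmethylated-read count
#' Poisson with mean `(1 - mu) * depth`, independently. Region structure
#' and truth are drawn like [simulate_methylseq()] (single library).
#'
#' @inheritParams simulate_methylseq
#' @return an `rrbs_dataset`: `regions` (list of `rrbs_region` with
#'   `c_count`/`t_count` per site), `truth`, `params`.
#' @export
simulate_rrbs <- function(depth = 50, n_regions = 155, mu_dist = mu_beta(),
                          seed = NULL, size_probs = region_size_probs()) {
  stopifnot(depth > 0)
  if (!is.null(seed)) set.seed(seed)
  st <- .sim_structure(n_regions, 1L, mu_dist, size_probs)
  regions <- vector("list", n_regions)
  for (g in seq_len(n_regions)) {
    k <- st$K[g]
    mu <- st$mu[g, 1]
    sites <- data.frame(site_id = sprintf("s%d", seq_len(k)),
                        pos = 10000L * g + 40L * (seq_len(k) - 1L),
                        c_count = rpois(k, mu * depth),
                        t_count = rpois(k, (1 - mu) * depth),
                        stringsAsFactors = FALSE)
    regions[[g]] <- structure(list(region_id = st$region_ids[g],
                                   chrom = "chrSim", sites = sites, K = k),
                              class = "rrbs_region")
  }
  truth <- data.frame(region_id = st$region_ids, library_id = "rrbs",
                      mu = st$mu[, 1], stringsAsFactors = FALSE)
  structure(list(regions = regions, truth = truth,
                 params = list(design = "rrbs", depth = depth,
                               n_regions = n_regions,
                               mu_dist = unclass(mu_dist),
                               size_probs = size_probs, seed = seed)),
            class = "rrbs_dataset")
}

#' @export
print.rrbs_dataset <- function(x, ...) {
  cat(sprintf("<rrbs_dataset> %d regions, %d sites\n", length(x$regions),
              sum(vapply(x$regions, function(r) r$K, integer(1)))))
  invisible(x)
}

#' Write / read RRBS site counts
#'
#' TSV with columns `chrom`, `pos`, `region_id`, `site_id`, `c_count`,
#' `t_count`.
#'
#' @param dataset an `rrbs_dataset` or list of `rrbs_region`s.
#' @param path file path.
#' @export
write_rrbs_counts <- function(dataset, path) {
  regions <- if (inherits(dataset, "rrbs_dataset")) dataset$regions else dataset
  rows <- do.call(rbind, lapply(regions, function(r) {
    data.frame(chrom = r$chrom, pos = r$sites$pos, region_id = r$region_id,
               site_id = r$sites$site_id, c_count = r$sites$c_count,
               t_count = r$sites$t_count, stringsAsFactors = FALSE)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rrbs_counts
#' @export
read_rrbs_counts <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "region_id", "site_id", "c_count", "t_count")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(sprintf("RRBS count file missing column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  .check_counts(df$c_count, "c_count")
  .check_counts(df$t_count, "t_count")
  idx <- split(seq_len(nrow(df)),
               factor(df$region_id, levels = unique(df$region_id)))
  lapply(names(idx), function(rid) {
    i <- idx[[rid]][order(df$pos[idx[[rid]]])]
    structure(list(region_id = rid, chrom = df$chrom[i][1],
                   sites = df[i, c("site_id", "pos", "c_count", "t_count")],
                   K = length(i)),
              class = "rrbs_region")
  })
}
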