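test_that("region sizes reproduce the genome-wide K distribution", {
  set.seed(1)
  k <- sample_region_sizes(1e5)
  expect_lt(abs(mean(k == 2) - 0.77), 0.005)
  expect_lt(abs(mean(k <= 5) - 0.95), 0.005)
  expect_true(all(k >= 2 & k <= 10))
  set.seed(2)
  expect_length(sample_region_sizes(1), 1)
  # configurable: single-site regions for site-level designs
  expect_true(all(sample_region_sizes(100, c(`1` = 1)) == 1))
})

test_that("Methyl-Seq generator obeys the thinning law", {
  n_sites_of <- function(ds) sum(vapply(ds$regions, function(r) r$K,
                                        integer(1)))
  all_y <- function(ds) unlist(lapply(ds$regions, function(r) r$hpaii))
  all_x <- function(ds) unlist(lapply(ds$regions, function(r) r$sites$mspi))

  ds0 <- simulate_methylseq(3000, 1, 50, mu_fixed(0), seed = 21,
                            size_probs = c(`1` = 1))
  expect_lt(abs(mean(all_y(ds0)) - 50), 3 * sqrt(50 / 3000))
  ds1 <- simulate_methylseq(500, 2, 50, mu_fixed(1), seed = 22)
  expect_true(all(all_y(ds1) == 0))
  ds5 <- simulate_methylseq(3000, 1, 50, mu_fixed(0.5), seed = 23,
                            size_probs = c(`1` = 1))
  expect_lt(abs(mean(all_y(ds5)) - 25), 3 * sqrt(25 / 3000))

  # MspI marginal is Poisson(depth): chi-square goodness of fit
  x <- all_x(simulate_methylseq(5000, 1, 10, seed = 24,
                                size_probs = c(`2` = 1)))
  breaks <- c(-Inf, 4:16, Inf)
  obs <- table(cut(x, breaks))
  expca <- diff(ppois(c(-Inf, 4:16, Inf), 10)) * length(x)
  pval <- pchisq(sum((as.vector(obs) - expca)^2 / expca),
                 df = length(expca) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.001)

  # truth covers every (region, library) pair, levels in [0,1]
  ds <- simulate_methylseq(20, 3, 50, seed = 25)
  expect_equal(nrow(ds$truth), 60)
  expect_true(all(ds$truth$mu >= 0 & ds$truth$mu <= 1))
  # deterministic under a fixed seed
  expect_identical(simulate_methylseq(20, 3, 50, seed = 25), ds)
})

test_that("binomial thinning variant matches the marginal law in mean", {
  ds <- simulate_methylseq(4000, 1, 40, mu_fixed(0.3), seed = 26,
                           thinning = "binomial", size_probs = c(`1` = 1))
  y <- unlist(lapply(ds$regions, function(r) r$hpaii))
  expect_lt(abs(mean(y) - 0.7 * 40), 3 * sqrt(0.7 * 40 / 4000))
})

test_that("discordant generator reduces to the basic one at sigma = 0", {
  a <- simulate_discordant(50, 0, n_datasets = 1, n_regions = 30,
                           n_libraries = 2, seed = 31)[[1]]
  b <- simulate_methylseq(30, 2, 50, seed = 31)
  expect_identical(a$regions, b$regions)
  expect_identical(a$truth, b$truth)
})

test_that("discordant HpaII depths follow the log-normal law", {
  dss <- simulate_discordant(30, 1, n_datasets = 1, n_regions = 1e4,
                             n_libraries = 1, seed = 32,
                             size_probs = c(`1` = 1))
  ld <- log(dss[[1]]$params$depth_hpaii)
  expect_lt(abs(var(ld) - 1), 0.05)                 # sigma^2 = 1 within 5%
  expect_lt(abs(median(exp(ld)) - 30), 1)           # log-normal median
  expect_lt(abs(mean(ld) - log(30)), 3 / sqrt(1e4))
})

test_that("technical replicates share truth but not counts", {
  pair <- simulate_replicates(50, n_regions = 100, n_libraries = 2,
                              seed = 33)
  expect_identical(pair$rep1$truth, pair$rep2$truth)
  y1 <- unlist(lapply(pair$rep1$regions, function(r) r$hpaii))
  y2 <- unlist(lapply(pair$rep2$regions, function(r) r$hpaii))
  expect_false(identical(y1, y2))
  # consistency limit: at very high depth TPE replicates agree
  deep <- simulate_replicates(1e5, n_regions = 100, n_libraries = 1,
                              seed = 34)
  e1 <- estimate_regions(deep$rep1, "tpe")
  e2 <- estimate_regions(deep$rep2, "tpe")
  expect_gt(consistency(e1$mu, e2$mu), 0.999)
})

test_that("correlated-site copula hits the target correlation and marginal", {
  ds1 <- simulate_correlated_sites(1, 30, n_sites = 200, seed = 35)
  m <- matrix(ds1$truth_sites$mu, nrow = 2)
  expect_equal(m[1, ], m[2, ])                      # comonotone at rho = 1
  ds <- simulate_correlated_sites(0.92, 30, n_sites = 2e4, seed = 36)
  m <- matrix(ds$truth_sites$mu, nrow = 2)
  expect_lt(abs(cor(m[1, ], m[2, ]) - 0.92), 0.01)
  # marginal preserved: two-sample KS against direct Beta draws
  set.seed(37)
  ref <- rbeta(1e4, 0.4, 0.4)
  expect_gt(suppressWarnings(ks.test(m[1, ], ref)$p.value), 0.01)
  # MspI counts fixed at the design depth
  expect_true(all(unlist(lapply(ds$regions,
                                function(r) r$sites$mspi)) == 30))
  expect_error(simulate_correlated_sites(1.2, 30), "\\[0, 1\\]")
})

test_that("RRBS generator splits coverage by methylation state", {
  all_ct <- function(ds) do.call(rbind, lapply(ds$regions,
                                               function(r) r$sites))
  ds1 <- simulate_rrbs(50, 200, mu_fixed(1), seed = 38)
  expect_true(all(all_ct(ds1)$t_count == 0))
  ds5 <- simulate_rrbs(50, 4000, mu_fixed(0.5), seed = 39,
                       size_probs = c(`1` = 1))
  ct <- all_ct(ds5)
  expect_lt(abs(mean(ct$c_count) / mean(ct$c_count + ct$t_count) - 0.5),
            3 * 0.5 / sqrt(sum(ct$c_count + ct$t_count)))
  expect_lt(abs(mean(ct$c_count + ct$t_count) - 50), 3 * sqrt(50 / 4000))
})

test_that("RRBS counts round-trip through TSV", {
  ds <- simulate_rrbs(50, 10, seed = 40)
  path <- tempfile(fileext = ".tsv")
  write_rrbs_counts(ds, path)
  again <- read_rrbs_counts(path)
  expect_equal(length(again), 10)
  expect_equal(again[[3]]$sites$c_count, ds$regions[[3]]$sites$c_count)
  expect_equal(estimate_regions(again, "rrbs"), estimate_regions(ds, "rrbs"))
})
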