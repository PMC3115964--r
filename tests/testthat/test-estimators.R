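test_that("binary call follows the mean-HpaII rule", {
  expect_equal(binary_call(c(2, 3)), 0)   # mean 2.5 > 1 -> unmethylated
  expect_equal(binary_call(c(0, 1)), 1)
  expect_equal(binary_call(c(1, 1)), 1)   # boundary: rule is strict >
  expect_error(binary_call(numeric(0)), "non-empty")
})

test_that("TPE matches its closed form and truncates at zero", {
  expect_equal(tpe(c(10, 10), c(5, 5)), 0.5)
  expect_equal(tpe(5, 8), 0)              # HpaII exceeds MspI -> truncated
  expect_equal(tpe(10, 0), 1)
  expect_equal(tpe(10, 4, c = 0.5), 0.2)  # bias-adjusted ratio
  expect_error(tpe(c(0, 0), c(1, 2)), "no MspI signal")
  expect_error(tpe(c(1, 2), 1), "equal length")
  expect_error(tpe(10, 5, c = 0), "positive")
})

test_that("TPE is bounded, hits the bounds only as specified, and is monotone", {
  set.seed(7)
  for (i in 1:200) {
    K <- sample(1:5, 1)
    x <- rpois(K, 20) + 1L
    y <- rpois(K, 15)
    cc <- runif(1, 0.3, 2)
    est <- tpe(x, y, cc)
    expect_gte(est, 0); expect_lte(est, 1)
    expect_equal(est == 1, sum(y) == 0)
    expect_equal(est == 0, sum(y) / cc >= sum(x))
    # monotone: more HpaII evidence can only lower the estimate,
    # more MspI evidence can only raise it (weakly, due to truncation)
    y2 <- y; y2[1] <- y2[1] + 3L
    expect_lte(tpe(x, y2, cc), est)
    x2 <- x; x2[1] <- x2[1] + 3L
    expect_gte(tpe(x2, y, cc), est)
  }
})

test_that("RRBS estimate pools counts and is symmetric under label swap", {
  expect_equal(rrbs_estimate(3, 1), 0.75)
  expect_equal(rrbs_estimate(0, 5), 0)
  expect_equal(rrbs_estimate(c(2, 6), c(2, 2)), 8 / 12)
  expect_error(rrbs_estimate(c(0, 0), c(0, 0)), "zero total")
  set.seed(8)
  for (i in 1:50) {
    cc <- rpois(3, 10); tt <- rpois(3, 10)
    if (sum(cc) + sum(tt) == 0) next
    expect_equal(rrbs_estimate(cc, tt), 1 - rrbs_estimate(tt, cc))
  }
})

test_that("depth-bias ratio is the HpaII/MspI tag-total ratio", {
  expect_equal(compute_depth_bias(10e6, 3e6), 0.3)
  expect_equal(compute_depth_bias(5, 5), 1)
  expect_error(compute_depth_bias(0, 5), "positive")
})

test_that("estimate_regions produces one row per region-library", {
  ds <- simulate_methylseq(n_regions = 12, n_libraries = 3, depth = 50,
                           seed = 31)
  for (method in c("tpe", "binary")) {
    est <- estimate_regions(ds, method)
    expect_equal(nrow(est), 36)
    expect_setequal(est$library_id, c("lib1", "lib2", "lib3"))
    expect_true(all(est$mu >= 0 & est$mu <= 1))
    expect_true(all(is.na(est$variance)))
  }
  expect_true(all(estimate_regions(ds, "binary")$mu %in% c(0, 1)))
})

test_that("per-library bias ratios reach the estimator", {
  ds <- simulate_methylseq(n_regions = 10, n_libraries = 2, depth = 60,
                           mu_dist = mu_fixed(0.5),
                           bias = c(1, 0.5), seed = 77)
  unadj <- estimate_regions(ds, "tpe")
  adj <- estimate_regions(ds, "tpe", bias = c(lib1 = 1, lib2 = 0.5))
  lib2 <- unadj$library_id == "lib2"
  # lib2 was sequenced at half depth: unadjusted estimates overshoot,
  # the adjusted ones recenter near the truth
  expect_gt(mean(unadj$mu[lib2]) - 0.5, 0.15)
  expect_lt(abs(mean(adj$mu[lib2]) - 0.5), 0.08)
  expect_equal(adj$mu[!lib2], unadj$mu[!lib2])
})

test_that("site-level recut preserves counts and expands truth", {
  ds <- simulate_methylseq(n_regions = 6, n_libraries = 2, depth = 50,
                           seed = 19)
  site_ds <- as_site_level(ds)
  expect_equal(length(site_ds$regions),
               sum(vapply(ds$regions, function(r) r$K, integer(1))))
  expect_true(all(vapply(site_ds$regions, function(r) r$K, integer(1)) == 1))
  r1 <- ds$regions[[1]]
  expanded <- site_ds$truth[grepl("^r0001_", site_ds$truth$region_id) &
                              site_ds$truth$library_id == "lib1", ]
  original <- ds$truth$mu[ds$truth$region_id == "r0001" &
                            ds$truth$library_id == "lib1"]
  expect_equal(expanded$mu, rep(original, r1$K))
  # counts survive the recut
  expect_equal(site_ds$regions[[1]]$sites$mspi, r1$sites$mspi[1])
})
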