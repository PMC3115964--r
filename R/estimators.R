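#' Binary methylation call from HpaII tag counts
#'
#' The original Methyl-Seq call: a region whose mean collapsed HpaII tag
#' count exceeds 1 is called unmethylated (`mu = 0`), otherwise methylated
#' (`mu = 1`). MspI counts enter only through the assayability filter.
#'
#' @param hpaii_counts the K collapsed HpaII counts of one region in one
#'   library.
#' @return 0 or 1.
#' @examples
#' binary_call(c(2, 3))  # mean 2.5 > 1 -> unmethylated, 0
#' binary_call(c(1, 1))  # mean exactly 1 -> methylated, 1
#' @export
binary_call <- function(hpaii_counts) {
  if (length(hpaii_counts) == 0) stop("`hpaii_counts` must be non-empty")
  .check_counts(hpaii_counts, "hpaii_counts")
  if (mean(hpaii_counts) > 1) 0 else 1
}

#' Truncated Proportional Estimate (TPE)
#'
#' Maximum-likelihood estimator of the region methylation level under the
#' Poisson-thinning count model: HpaII tags are the surviving fraction
#' (1 - mu) of the tags the MspI library would see. The ratio
#' `sum(y)/sum(x)` estimates the unmethylated proportion; because of
#' sampling noise it can exceed 1, in which case the estimate is truncated
#' to 0. With a sequencing-depth bias ratio `c` (HpaII depth / MspI depth,
#' see [compute_depth_bias()]) the observed ratio is divided by `c` first,
#' so `c < 1` (HpaII sequenced shallower) raises the estimate.
#'
#' @param x MspI collapsed counts (length K).
#' @param y HpaII collapsed counts for one library (length K).
#' @param c depth-bias ratio, HpaII over MspI; 1 means no bias.
#' @return point estimate in \[0, 1\].
#' @examples
#' tpe(c(10, 10), c(5, 5))      # 0.5
#' tpe(5, 8)                    # ratio > 1, truncated to 0
#' tpe(10, 4, c = 0.5)          # 1 - (0.4)/0.5 = 0.2
#' @export
tpe <- function(x, y, c = 1) {
  if (length(x) != length(y) || length(x) < 1) {
    stop("`x` and `y` must be non-empty and of equal length")
  }
  .check_counts(x, "x")
  .check_counts(y, "y")
  if (!is.finite(c) || c <= 0) stop("`c` must be a positive finite number")
  if (sum(x) == 0) {
    stop("undefined estimate: no MspI signal in region (sum(x) == 0)")
  }
  max(0, 1 - (sum(y) / sum(x)) / c)
}

#' RRBS proportional estimate
#'
#' In bisulfite sequencing a methylated cytosine reads 'C' and an
#' unmethylated one reads 'T'; the methylation level of a site is
#' `C/(C+T)`, and a region pools counts: `sum(C)/sum(C+T)`.
#'
#' @param c_count tags reading 'C' (methylated), per site.
#' @param t_count tags reading 'T' (unmethylated), per site.
#' @return point estimate in \[0, 1\].
#' @examples
#' rrbs_estimate(3, 1)               # 0.75
#' rrbs_estimate(c(2, 6), c(2, 2))   # 8/12
#' @export
rrbs_estimate <- function(c_count, t_count) {
  if (length(c_count) != length(t_count) || length(c_count) < 1) {
    stop("`c_count` and `t_count` must be non-empty and of equal length")
  }
  .check_counts(c_count, "c_count")
  .check_counts(t_count, "t_count")
  tot <- sum(c_count) + sum(t_count)
  if (tot == 0) stop("undefined estimate: zero total RRBS coverage")
  sum(c_count) / tot
}

#' Library-wide sequencing-depth bias ratio
#'
#' MspI libraries are typically sequenced deeper than HpaII libraries.
#' Lacking per-region bias information, the genome-wide totals of CGG tags
#' aligned to MspI sites serve as the reference: the effective
#' HpaII-to-MspI depth ratio is the ratio of the two library totals.
#' Because HpaII tag yield also depends on methylation itself, the
#' adjustment is approximate.
#'
#' @param total_mspi_cgg_tags genome-wide CGG-aligned tag total of the
#'   MspI library.
#' @param total_hpaii_cgg_tags same for one HpaII library.
#' @return the ratio `c` (> 0); `c = 1` means no bias.
#' @examples
#' compute_depth_bias(10e6, 3e6)  # 0.3
#' @export
compute_depth_bias <- function(total_mspi_cgg_tags, total_hpaii_cgg_tags) {
  if (!is.finite(total_mspi_cgg_tags) || !is.finite(total_hpaii_cgg_tags) ||
      total_mspi_cgg_tags <= 0 || total_hpaii_cgg_tags <= 0) {
    stop("both tag totals must be positive")
  }
  total_hpaii_cgg_tags / total_mspi_cgg_tags
}

#' Estimate methylation levels for all regions and libraries
#'
#' Applies one estimator per (region, library) pair. Methyl-Seq input is a
#' list of regions (from [read_tagcounts()] or [simulate_methylseq()]`$regions`)
#' or a `methylseq_dataset`; RRBS input is an `rrbs_dataset` or list of
#' RRBS regions, with `method = "rrbs"`.
#'
#' @param x regions, `methylseq_dataset`, or `rrbs_dataset`.
#' @param method one of `"tpe"`, `"binary"`, `"bayes"`, `"rrbs"`.
#' @param bias named numeric vector of per-library depth-bias ratios
#'   (default: no bias, `c = 1` for every library).
#' @param config a [bayes_config()] (used for `method = "bayes"`).
#' @param seed integer; for `method = "bayes"`, per-fit seeds are derived
#'   deterministically from it so the full table is reproducible.
#' @return data.frame with columns `region_id`, `library_id`, `method`,
#'   `mu`, `variance` (`NA` unless Bayesian) and, for Bayesian fits,
#'   `rhat`.
#' @export
estimate_regions <- function(x, method = c("tpe", "binary", "bayes", "rrbs"),
                             bias = NULL, config = bayes_config(),
                             seed = NULL) {
  method <- match.arg(method)
  regions <- if (inherits(x, c("methylseq_dataset", "rrbs_dataset")))
    x$regions else x
  stopifnot(length(regions) > 0)

  if (method == "rrbs") {
    out <- do.call(rbind, lapply(regions, function(r) {
      data.frame(region_id = r$region_id, library_id = "rrbs",
                 method = "rrbs",
                 mu = rrbs_estimate(r$sites$c_count, r$sites$t_count),
                 variance = NA_real_, stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    return(out)
  }

  libs <- colnames(regions[[1]]$hpaii)
  cvec <- rep(1, length(libs)); names(cvec) <- libs
  if (!is.null(bias)) {
    if (is.data.frame(bias)) bias <- stats::setNames(bias$c, bias$library_id)
    cvec[names(bias)] <- bias
  }

  grid <- expand.grid(g = seq_along(regions), lib = libs,
                      stringsAsFactors = FALSE)
  if (method == "bayes") {
    rows <- vector("list", nrow(grid))
    for (k in seq_len(nrow(grid))) {
      r <- regions[[grid$g[k]]]
      lib <- grid$lib[k]
      cfg <- config
      cfg$seed <- if (is.null(seed)) NULL else .derive_seed(seed, k)
      fit <- fit_bayes_region(r$sites$mspi, r$hpaii[, lib], c = cvec[[lib]],
                              config = cfg)
      rows[[k]] <- data.frame(region_id = r$region_id, library_id = lib,
                              method = "bayes", mu = fit$mu_mean,
                              variance = fit$mu_variance, rhat = fit$rhat,
                              stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
  } else {
    est_fun <- switch(method,
      tpe = function(r, lib) tpe(r$sites$mspi, r$hpaii[, lib],
                                 c = cvec[[lib]]),
      binary = function(r, lib) binary_call(r$hpaii[, lib]))
    out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(k) {
      r <- regions[[grid$g[k]]]
      data.frame(region_id = r$region_id, library_id = grid$lib[k],
                 method = method, mu = est_fun(r, grid$lib[k]),
                 variance = NA_real_, stringsAsFactors = FALSE)
    }))
  }
  rownames(out) <- NULL
  out
}

## deterministic per-task seed derivation, kept within 32-bit range
.derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 9973) %% 2147483629)
}

#' Re-cut a dataset to site-level regions
#'
#' Returns the same counts with every site promoted to its own
#' single-site region (region id `<region>_<site>`), for comparing
#' site-level with region-level quantification. Truth, when present, is
#' expanded to per-site truth.
#'
#' @param x a `methylseq_dataset` or list of regions.
#' @return same type as the input.
#' @export
as_site_level <- function(x) {
  is_ds <- inherits(x, "methylseq_dataset")
  regions <- if (is_ds) x$regions else x
  out <- list()
  for (r in regions) {
    for (i in seq_len(r$K)) {
      rid <- sprintf("%s_%s", r$region_id, r$sites$site_id[i])
      out[[length(out) + 1L]] <- new_region(
        rid, r$chrom, r$sites[i, , drop = FALSE],
        hpaii = r$hpaii[i, , drop = FALSE],
        hpaii_fwd = if (!is.null(r$hpaii_fwd))
          r$hpaii_fwd[i, , drop = FALSE] else NULL,
        hpaii_rev = if (!is.null(r$hpaii_rev))
          r$hpaii_rev[i, , drop = FALSE] else NULL)
    }
  }
  if (!is_ds) return(out)
  truth <- x$truth
  if (!is.null(x$truth_sites)) {
    ts <- x$truth_sites
    truth <- data.frame(
      region_id = sprintf("%s_%s", ts$region_id, ts$site_id),
      library_id = ts$library_id, mu = ts$mu, stringsAsFactors = FALSE)
  } else {
    expand <- lapply(regions, function(r) {
      tr <- truth[truth$region_id == r$region_id, , drop = FALSE]
      do.call(rbind, lapply(seq_len(r$K), function(i) {
        data.frame(region_id = sprintf("%s_%s", r$region_id,
                                       r$sites$site_id[i]),
                   library_id = tr$library_id, mu = tr$mu,
                   stringsAsFactors = FALSE)
      }))
    })
    truth <- do.call(rbind, expand)
  }
  rownames(truth) <- NULL
  structure(list(regions = out, truth = truth, params = x$params),
            class = "methylseq_dataset")
}
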