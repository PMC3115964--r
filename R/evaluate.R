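#' Williams t-test for two dependent correlations sharing one variable
#'
#' Tests whether two estimators correlate equally with the same reference
#' (truth or gold-standard beta values). With `r1 = cor(est1, ref)`,
#' `r2 = cor(est2, ref)` and `r12 = cor(est1, est2)` over `n` paired
#' observations, the Williams/Steiger statistic is
#' \deqn{t = (r1 - r2) \sqrt{\frac{(n-1)(1+r12)}
#'   {2\frac{n-1}{n-3}|R| + \bar r^2 (1-r12)^3}}}
#' with \eqn{|R| = 1 - r1^2 - r2^2 - r12^2 + 2 r1 r2 r12} and
#' \eqn{\bar r = (r1 + r2)/2}, referred to a t distribution on `n - 3`
#' degrees of freedom (two-sided).
#'
#' @param r1,r2 correlations of the two estimators with the shared
#'   reference.
#' @param r12 correlation between the two estimators.
#' @param n number of paired observations (>= 4).
#' @return list with `t`, `df`, `p_value`.
#' @export
dependent_corr_test <- function(r1, r2, r12, n) {
  stopifnot(abs(r1) <= 1, abs(r2) <= 1, abs(r12) <= 1, n >= 4)
  detR <- 1 - r1^2 - r2^2 - r12^2 + 2 * r1 * r2 * r12
  if (detR <= 0) {
    stop("inconsistent correlations: implied correlation matrix is not positive definite")
  }
  if (r1 == r2) {
    return(list(t = 0, df = n - 3, p_value = 1))
  }
  rbar <- (r1 + r2) / 2
  tstat <- (r1 - r2) * sqrt((n - 1) * (1 + r12) /
    (2 * ((n - 1) / (n - 3)) * detR + rbar^2 * (1 - r12)^3))
  list(t = tstat, df = n - 3, p_value = 2 * pt(-abs(tstat), df = n - 3))
}

#' ROC area under the curve against dichotomized beta values
#'
#' Gold-standard microarray beta values are dichotomized at `threshold`
#' (default 0.6: above = methylated, below = unmethylated; values exactly
#' at the threshold are dropped), and the AUC of the continuous predictor
#' is the normalized Mann-Whitney statistic, counting ties as 1/2. The
#' historical HpaII-count predictor is *high* for unmethylated regions, so
#' it must be scored with `orientation = "lower_is_methylated"`; estimated
#' methylation levels use the default.
#'
#' @param predictor continuous predictions.
#' @param gold_beta gold-standard beta values (same length).
#' @param threshold dichotomization cutoff (default 0.6).
#' @param orientation whether larger predictor values indicate
#'   methylation.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(predictor, gold_beta, threshold = 0.6,
                    orientation = c("higher_is_methylated",
                                    "lower_is_methylated")) {
  orientation <- match.arg(orientation)
  if (length(predictor) != length(gold_beta)) {
    stop("`predictor` and `gold_beta` must have the same length")
  }
  keep <- gold_beta != threshold & !is.na(gold_beta) & !is.na(predictor)
  predictor <- predictor[keep]
  labels <- gold_beta[keep] > threshold
  if (!any(labels) || all(labels)) {
    stop("gold standard has only one class after dichotomization")
  }
  if (orientation == "lower_is_methylated") predictor <- -predictor
  r <- rank(predictor)  # midranks handle ties as 1/2
  n1 <- sum(labels); n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Replicate consistency
#'
#' Pearson correlation between paired estimates from technical
#' replicates; `NA` (with a warning) when either vector is constant.
#'
#' @param est_a,est_b equal-length paired estimates.
#' @return Pearson correlation, or `NA` if undefined.
#' @export
consistency <- function(est_a, est_b) {
  if (length(est_a) != length(est_b)) {
    stop("`est_a` and `est_b` must have the same length")
  }
  if (sd(est_a) == 0 || sd(est_b) == 0) {
    warning("consistency undefined: zero variance in one replicate")
    return(NA_real_)
  }
  cor(est_a, est_b)
}

#' Background-normalized Infinium beta value
#'
#' Subtracts the median of the negative-control probes from the
#' methylated and unmethylated channel intensities (flooring at zero) and
#' returns `b/(a + b)`. When both channels are floored the beta value is
#' undefined and `NA` is returned — missingness is a value here, not an
#' error. Channel-specific control medians are supported through
#' `neg_ctrl_median_unmeth`.
#'
#' @param meth,unmeth raw probe intensities (vectorized).
#' @param neg_ctrl_median negative-control median for the methylated
#'   channel (and, by default, the unmethylated channel).
#' @param neg_ctrl_median_unmeth optional separate control median for the
#'   unmethylated channel.
#' @return beta values in \[0, 1\], `NA` where undefined.
#' @examples
#' infinium_normalize(1000, 1000, 0)     # 0.5
#' infinium_normalize(300, 300, 400)     # NA, both channels floored
#' @export
infinium_normalize <- function(meth, unmeth, neg_ctrl_median,
                               neg_ctrl_median_unmeth = neg_ctrl_median) {
  b <- pmax(meth - neg_ctrl_median, 0)
  a <- pmax(unmeth - neg_ctrl_median_unmeth, 0)
  out <- ifelse(a + b == 0, NA_real_, b / (a + b))
  out
}

#' Score estimates against truth (and optionally a gold standard)
#'
#' Joins an estimate table to a truth table on (region_id, library_id)
#' and reports, per method, the Pearson and Spearman correlations with
#' truth, the number of levels, and — when `gold_beta = TRUE` — the AUC
#' against the truth dichotomized at `threshold`. Levels are pooled
#' across libraries by default; `by_library = TRUE` reports per library.
#'
#' @param estimates data.frame from [estimate_regions()] (possibly several
#'   methods row-bound together).
#' @param truth data.frame with `region_id`, `library_id`, `mu`.
#' @param gold_beta compute AUC against dichotomized truth.
#' @param threshold dichotomization cutoff for the AUC.
#' @param by_library report per-library rows instead of pooling.
#' @return data.frame with `method`, (`library_id`,) `pearson`,
#'   `spearman`, `auc`, `n`.
#' @export
evaluate_estimates <- function(estimates, truth, gold_beta = FALSE,
                               threshold = 0.6, by_library = FALSE) {
  merged <- merge(estimates, truth, by = c("region_id", "library_id"),
                  suffixes = c("", "_true"))
  if (nrow(merged) == 0) stop("no (region_id, library_id) pairs in common")
  groups <- if (by_library) c("method", "library_id") else "method"
  key <- interaction(merged[groups], drop = TRUE)
  out <- lapply(split(merged, key), function(d) {
    auc <- if (gold_beta) {
      roc_auc(d$mu, d$mu_true, threshold = threshold)
    } else NA_real_
    cbind(d[1, groups, drop = FALSE],
          data.frame(pearson = cor(d$mu, d$mu_true),
                     spearman = cor(d$mu, d$mu_true, method = "spearman"),
                     auc = auc, n = nrow(d)))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
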