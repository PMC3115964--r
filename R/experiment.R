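#' Experiment configuration
#'
#' One JSON-serializable document holding everything needed to re-run a
#' benchmark experiment: the design name, generator and estimator
#' parameters, a global seed (per-stage seeds are derived from it
#' deterministically), an output directory and a scale factor. The scale
#' factor multiplies region counts and dataset replicates so small runs
#' finish in seconds while the full design stays one flag away.
#'
#' @param design one of `"basic"` (constant-depth accuracy benchmark),
#'   `"depth-sweep"` (replicate consistency over depths),
#'   `"discordance"` (log-normal MspI/HpaII depth discordance),
#'   `"correlated"` (site- vs region-level at two depths),
#'   `"replicates"` (one technical-replicate pair), `"rrbs"`
#'   (RRBS vs Methyl-Seq variance profile).
#' @param seed global integer seed.
#' @param out_dir output directory (created when the experiment runs);
#'   `NULL` returns results without writing files.
#' @param scale scale factor in (0, 1\] applied to region counts and
#'   dataset replicates.
#' @param ... design-specific overrides (e.g. `depth`, `sigma_levels`,
#'   `n_datasets`, `depths`, `rho_levels`, `n_regions`, `n_libraries`,
#'   `mu_alpha`, `mu_beta_par`, `bayes`: a [bayes_config()]).
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(design = c("basic", "depth-sweep",
                                         "discordance", "correlated",
                                         "replicates", "rrbs"),
                              seed = 1L, out_dir = NULL, scale = 1, ...) {
  design <- match.arg(design)
  stopifnot(scale > 0, scale <= 1)
  defaults <- list(n_regions = 155L, n_libraries = 6L, depth = 50,
                   mu_alpha = 0.4, mu_beta_par = 0.4,
                   sigma_levels = c(0, 0.5, 1), depth_mspi = 30,
                   n_datasets = 10L, depths = c(40, 80, 150, 300),
                   rho_levels = c(0.92, 1), rho_depths = c(30, 300),
                   n_sites = 2000L,
                   bayes = bayes_config())
  extras <- list(...)
  bayes <- if (!is.null(extras$bayes)) extras$bayes else defaults$bayes
  stopifnot(inherits(bayes, "bayes_config"))
  extras$bayes <- NULL
  defaults$bayes <- NULL
  # modifyList would silently delete NULL-valued fields (e.g. an unset
  # sampler seed), so the bayes config bypasses it
  cfg <- modifyList(defaults, extras)
  cfg$bayes <- bayes
  cfg$design <- design
  cfg$seed <- as.integer(seed)
  cfg$out_dir <- out_dir
  cfg$scale <- scale
  structure(cfg, class = "experiment_config")
}

#' Serialize / restore an experiment configuration
#'
#' Configs round-trip losslessly through JSON so every experiment is
#' re-runnable from its sidecar alone.
#'
#' @param config an [experiment_config()].
#' @param path JSON file path.
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  x <- unclass(config)
  x$bayes <- unclass(x$bayes)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  bayes <- x$bayes
  x$bayes <- NULL
  cfg <- do.call(experiment_config,
                 c(x[setdiff(names(x), c("design", "seed", "out_dir", "scale"))],
                   list(design = x$design, seed = x$seed,
                        out_dir = x$out_dir, scale = x$scale)))
  cfg$bayes <- do.call(bayes_config, c(
    bayes[setdiff(names(bayes), c("fix_r", "mode"))],
    list(mode = bayes$mode,
         fix_r = if (is.null(bayes$fix_r) || bayes$fix_r <= 0) NULL
                 else bayes$fix_r)))
  cfg
}

.scale_n <- function(n, scale) max(1L, as.integer(round(n * scale)))

#' Run a benchmark experiment end to end
#'
#' Chains simulate -> estimate -> evaluate for the configured design,
#' writes (when `out_dir` is set) the simulated tag counts, the truth
#' table, the estimate tables, the evaluation report (JSON) and the
#' config sidecar, and logs progress with the seed and package version to
#' stderr. An identical config yields identical outputs.
#'
#' @param config an [experiment_config()].
#' @return the evaluation report (a list), invisibly when files are
#'   written.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  designs <- c("basic", "depth-sweep", "discordance", "correlated",
               "replicates", "rrbs")
  if (!config$design %in% designs) {
    stop(sprintf("unknown design '%s'; valid designs: %s", config$design,
                 paste(designs, collapse = ", ")))
  }
  message(sprintf("[methylquant %s] experiment '%s', seed %d, scale %g",
                  as.character(packageVersion("methylquant")),
                  config$design, config$seed, config$scale))
  report <- switch(config$design,
                   "basic" = .exp_basic(config),
                   "depth-sweep" = .exp_depth_sweep(config),
                   "discordance" = .exp_discordance(config),
                   "correlated" = .exp_correlated(config),
                   "replicates" = .exp_replicates(config),
                   "rrbs" = .exp_rrbs(config))
  report$design <- config$design
  report$seed <- config$seed
  report$package_version <- as.character(packageVersion("methylquant"))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_experiment_config(config, file.path(config$out_dir, "config.json"))
    jsonlite::write_json(report, file.path(config$out_dir, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "rows")
    return(invisible(report))
  }
  report
}

.mu_dist_of <- function(config) mu_beta(config$mu_alpha, config$mu_beta_par)

.write_ds <- function(config, ds, stem) {
  if (is.null(config$out_dir)) return(invisible(NULL))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(ds, "rrbs_dataset")) {
    write_rrbs_counts(ds, file.path(config$out_dir,
                                    sprintf("%s_counts.tsv", stem)))
  } else {
    write_tagcounts(ds$regions, file.path(config$out_dir,
                                          sprintf("%s_counts.tsv", stem)))
  }
  write.table(ds$truth, file.path(config$out_dir,
                                  sprintf("%s_truth.tsv", stem)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

.estimate_both <- function(ds, config, stage) {
  est_t <- estimate_regions(ds, "tpe")
  est_b <- estimate_regions(ds, "bayes", config = config$bayes,
                            seed = .derive_seed(config$seed, stage))
  list(tpe = est_t, bayes = est_b)
}

.exp_basic <- function(config) {
  n_regions <- .scale_n(config$n_regions, config$scale)
  ds <- simulate_methylseq(n_regions, config$n_libraries, config$depth,
                           .mu_dist_of(config),
                           seed = .derive_seed(config$seed, 1))
  .write_ds(config, ds, "basic")
  est <- .estimate_both(ds, config, 2)
  est$binary <- estimate_regions(ds, "binary")
  core_cols <- c("region_id", "library_id", "method", "mu", "variance")
  all_est <- do.call(rbind, lapply(est, function(d) d[core_cols]))
  if (!is.null(config$out_dir)) {
    write_estimates(all_est, file.path(config$out_dir, "basic_estimates.tsv"))
  }
  ev <- evaluate_estimates(all_est, ds$truth, gold_beta = TRUE)
  merged <- merge(merge(est$bayes[c("region_id", "library_id", "mu")],
                        est$tpe[c("region_id", "library_id", "mu")],
                        by = c("region_id", "library_id"),
                        suffixes = c("_bayes", "_tpe")),
                  ds$truth, by = c("region_id", "library_id"))
  ct <- dependent_corr_test(cor(merged$mu_bayes, merged$mu),
                            cor(merged$mu_tpe, merged$mu),
                            cor(merged$mu_bayes, merged$mu_tpe),
                            nrow(merged))
  list(evaluation = ev,
       correlation_gap = cor(merged$mu_bayes, merged$mu) -
         cor(merged$mu_tpe, merged$mu),
       gap_test = ct, n_levels = nrow(merged))
}

.exp_depth_sweep <- function(config) {
  n_regions <- .scale_n(config$n_regions, config$scale)
  rows <- list()
  for (i in seq_along(config$depths)) {
    depth <- config$depths[i]
    pair <- simulate_replicates(depth, n_regions, config$n_libraries,
                                .mu_dist_of(config),
                                seed = .derive_seed(config$seed, 10 + i))
    for (method in c("tpe", "bayes")) {
      ea <- estimate_regions(pair$rep1, method, config = config$bayes,
                             seed = .derive_seed(config$seed, 100 + i))
      eb <- estimate_regions(pair$rep2, method, config = config$bayes,
                             seed = .derive_seed(config$seed, 200 + i))
      rows[[length(rows) + 1L]] <- data.frame(
        depth = depth, method = method,
        consistency = consistency(ea$mu, eb$mu))
    }
  }
  list(consistency = do.call(rbind, rows))
}

.exp_discordance <- function(config) {
  n_regions <- .scale_n(config$n_regions, config$scale)
  n_datasets <- .scale_n(config$n_datasets, config$scale)
  rows <- list()
  for (i in seq_along(config$sigma_levels)) {
    sigma <- config$sigma_levels[i]
    # same per-dataset seed base across sigma levels: the sweep is paired
    # (identical truth tables per dataset index), and sigma = 0 matches
    # the 'basic' design's dataset under the same global seed
    ds_list <- simulate_discordant(config$depth_mspi, sigma, n_datasets,
                                   n_regions, config$n_libraries,
                                   .mu_dist_of(config),
                                   seed = .derive_seed(config$seed, 1))
    for (d in seq_along(ds_list)) {
      est <- .estimate_both(ds_list[[d]], config, 400 + 10 * i + d)
      for (method in names(est)) {
        m <- merge(est[[method]], ds_list[[d]]$truth,
                   by = c("region_id", "library_id"),
                   suffixes = c("", "_true"))
        rows[[length(rows) + 1L]] <- data.frame(
          sigma = sigma, dataset = d, method = method,
          pearson = cor(m$mu, m$mu_true))
      }
    }
  }
  detail <- do.call(rbind, rows)
  mean_tab <- aggregate(pearson ~ sigma + method, detail, mean)
  list(by_dataset = detail, mean_correlation = mean_tab)
}

.exp_correlated <- function(config) {
  n_sites <- .scale_n(config$n_sites, config$scale)
  n_sites <- n_sites + n_sites %% 2
  rows <- list()
  stage <- 0L
  for (depth in config$rho_depths) {
    for (rho in config$rho_levels) {
      stage <- stage + 1L
      ds <- simulate_correlated_sites(rho, depth, n_sites,
                                      .mu_dist_of(config),
                                      seed = .derive_seed(config$seed,
                                                          500 + stage))
      site_ds <- as_site_level(ds)
      for (level in c("region", "site")) {
        est <- estimate_regions(if (level == "region") ds else site_ds,
                                "bayes", config = config$bayes,
                                seed = .derive_seed(config$seed,
                                                    600 + stage))
        if (level == "region") {
          ts <- ds$truth_sites
          expanded <- merge(ts, est[c("region_id", "mu")],
                            by = "region_id", suffixes = c("_true", "_est"))
          r <- cor(expanded$mu_est, expanded$mu_true)
        } else {
          m <- merge(est, site_ds$truth, by = c("region_id", "library_id"),
                     suffixes = c("", "_true"))
          r <- cor(m$mu, m$mu_true)
        }
        rows[[length(rows) + 1L]] <- data.frame(depth = depth, rho = rho,
                                                level = level, pearson = r)
      }
    }
  }
  list(site_vs_region = do.call(rbind, rows))
}

.exp_replicates <- function(config) {
  n_regions <- .scale_n(config$n_regions, config$scale)
  pair <- simulate_replicates(config$depth, n_regions, config$n_libraries,
                              .mu_dist_of(config),
                              seed = .derive_seed(config$seed, 700))
  .write_ds(config, pair$rep1, "rep1")
  .write_ds(config, pair$rep2, "rep2")
  out <- list()
  for (method in c("tpe", "bayes")) {
    ea <- estimate_regions(pair$rep1, method, config = config$bayes,
                           seed = .derive_seed(config$seed, 701))
    eb <- estimate_regions(pair$rep2, method, config = config$bayes,
                           seed = .derive_seed(config$seed, 702))
    out[[method]] <- consistency(ea$mu, eb$mu)
  }
  list(consistency = out)
}

.exp_rrbs <- function(config) {
  n_regions <- .scale_n(config$n_regions, config$scale)
  rrbs <- simulate_rrbs(config$depth, n_regions, .mu_dist_of(config),
                        seed = .derive_seed(config$seed, 800))
  mseq <- simulate_methylseq(n_regions, 1, config$depth, .mu_dist_of(config),
                             seed = .derive_seed(config$seed, 801))
  .write_ds(config, rrbs, "rrbs")
  .write_ds(config, mseq, "methylseq")
  est_r <- estimate_regions(rrbs, "rrbs")
  est_t <- estimate_regions(mseq, "tpe")
  bin_table <- function(est, truth) {
    m <- merge(est, truth, by = c("region_id", "library_id"),
               suffixes = c("", "_true"))
    bins <- cut(m$mu_true, c(-Inf, 0.2, 0.8, Inf),
                labels = c("mu<0.2", "0.2<=mu<=0.8", "mu>0.8"))
    agg <- aggregate(list(sd_error = m$mu - m$mu_true),
                     list(mu_bin = bins), sd)
    agg$n <- as.vector(table(bins)[agg$mu_bin])
    agg
  }
  list(variance_by_mu_bin = list(rrbs = bin_table(est_r, rrbs$truth),
                                 methylseq_tpe = bin_table(est_t, mseq$truth)),
       evaluation = rbind(evaluate_estimates(est_r, rrbs$truth),
                          evaluate_estimates(est_t, mseq$truth)))
}
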