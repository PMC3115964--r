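#' Collapse forward/reverse strand tag counts
#'
#' At an unmethylated CCGG cleavage site the forward and reverse tags both
#' witness the same digestion event, but local fragment geometry (distance
#' to the next cleaved site) can suppress one direction entirely. Summing
#' the two strands would double-count sites flanked by two nearby cleaved
#' sites, so the larger of the two counts is used as the site count.
#'
#' @param fwd,rev non-negative integer tag counts (vectorized).
#' @return the per-site collapsed count, `pmax(fwd, rev)`.
#' @examples
#' collapse_strand(3, 5)
#' @export
collapse_strand <- function(fwd, rev) {
  if (length(fwd) != length(rev)) {
    stop("`fwd` and `rev` must have the same length")
  }
  .check_counts(fwd, "fwd")
  .check_counts(rev, "rev")
  pmax(fwd, rev)
}

#' Is a CCGG site assayable?
#'
#' A cleavage site is quantifiable only where the methylation-insensitive
#' MspI library saw it: the rule is coverage by `min_reads` (default 4) or
#' more MspI reads on either the forward or the reverse strand.
#'
#' @param mspi_fwd,mspi_rev MspI tag counts per strand (vectorized).
#' @param min_reads assayability threshold on either strand (default 4).
#' @return logical vector.
#' @examples
#' is_assayable(4, 0)  # TRUE
#' is_assayable(3, 3)  # FALSE
#' @export
is_assayable <- function(mspi_fwd, mspi_rev, min_reads = 4) {
  .check_counts(mspi_fwd, "mspi_fwd")
  .check_counts(mspi_rev, "mspi_rev")
  mspi_fwd >= min_reads | mspi_rev >= min_reads
}

#' Group sites into regions by genomic gap
#'
#' Stand-in for published region definitions: consecutive sites (sorted by
#' position, within one chromosome) are chained into a region while the gap
#' to the previous site is at most `max_gap` base pairs (default 75, the
#' upper end of the Methyl-Seq fragment size selection window). Supply
#' explicit `region_id`s instead whenever the original region definitions
#' are available.
#'
#' @param pos sorted 1-based site positions on one chromosome.
#' @param max_gap maximum within-region gap in bp.
#' @return integer vector of region indices (1, 2, ...).
#' @export
group_sites_by_gap <- function(pos, max_gap = 75) {
  if (length(pos) == 0) return(integer(0))
  if (is.unsorted(pos)) stop("`pos` must be sorted increasingly")
  cumsum(c(TRUE, diff(pos) > max_gap))
}

## internal constructor; `sites` carries site_id, pos, mspi_fwd, mspi_rev,
## mspi (collapsed); hpaii* are K x n_libraries matrices with library ids
## as column names.
new_region <- function(region_id, chrom, sites, hpaii,
                       hpaii_fwd = NULL, hpaii_rev = NULL) {
  structure(
    list(region_id = as.character(region_id), chrom = as.character(chrom),
         sites = sites, hpaii = hpaii,
         hpaii_fwd = hpaii_fwd, hpaii_rev = hpaii_rev,
         K = nrow(sites)),
    class = "methyl_region")
}

#' @export
print.methyl_region <- function(x, ...) {
  cat(sprintf("<methyl_region> %s (%s), K = %d sites, %d HpaII libraries\n",
              x$region_id, x$chrom, x$K, ncol(x$hpaii)))
  invisible(x)
}

#' Library identifiers of a region or dataset
#' @param x a `methyl_region` or a `methylseq_dataset`.
#' @return character vector of HpaII library ids.
#' @export
region_libraries <- function(x) {
  if (inherits(x, "methylseq_dataset")) x <- x$regions[[1]]
  colnames(x$hpaii)
}

.check_counts <- function(x, name) {
  if (anyNA(x) || any(x < 0)) {
    stop(sprintf("`%s` must be non-negative and non-missing", name))
  }
  if (any(x != floor(x))) {
    stop(sprintf("`%s` must be integer-valued", name))
  }
  invisible(TRUE)
}

.validate_region <- function(r) {
  stopifnot(inherits(r, "methyl_region"), r$K >= 1,
            nrow(r$sites) == r$K, all(r$sites$pos >= 1),
            !is.unsorted(r$sites$pos))
  .check_counts(r$sites$mspi, "mspi")
  .check_counts(as.vector(r$hpaii), "hpaii")
  invisible(TRUE)
}

#' Read a tag-count table into regions
#'
#' Reads the tab-delimited Methyl-Seq tag-count dialect: one row per CCGG
#' site with columns `chrom`, `pos` (1-based), `region_id`, `site_id`,
#' `mspi_fwd`, `mspi_rev`, and one `hpaii_<lib>_fwd` / `hpaii_<lib>_rev`
#' pair per HpaII library. Strand counts are collapsed with
#' [collapse_strand()] (MspI once, HpaII per library), non-assayable sites
#' (see [is_assayable()]) are dropped, and regions left empty are removed.
#' Row order within a region follows genomic position.
#'
#' @param path file path.
#' @param assayable_min MspI single-strand read threshold (default 4);
#'   set `drop_unassayable = FALSE` to keep all sites.
#' @param drop_unassayable drop sites failing the assayability rule.
#' @return list of `methyl_region` objects.
#' @export
read_tagcounts <- function(path, assayable_min = 4, drop_unassayable = TRUE) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  base_cols <- c("chrom", "pos", "region_id", "site_id",
                 "mspi_fwd", "mspi_rev")
  missing_cols <- setdiff(base_cols, names(df))
  if (length(missing_cols)) {
    stop(sprintf("tag-count file %s is missing column(s): %s",
                 path, paste(missing_cols, collapse = ", ")))
  }
  hp <- grep("^hpaii_.+_(fwd|rev)$", names(df), value = TRUE)
  libs <- unique(sub("^hpaii_(.+)_(fwd|rev)$", "\\1", hp))
  if (length(libs) == 0) stop("no hpaii_<lib>_fwd/_rev columns found")
  for (lib in libs) {
    for (side in c("fwd", "rev")) {
      cn <- sprintf("hpaii_%s_%s", lib, side)
      if (!cn %in% names(df)) {
        stop(sprintf("missing column: %s", cn))
      }
    }
  }

  count_cols <- c("pos", "mspi_fwd", "mspi_rev", hp)
  for (cn in count_cols) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (cn == "pos") bad <- which(is.na(v) | v < 1 | v != floor(v))
    if (length(bad)) {
      stop(sprintf("column %s: invalid count '%s' at line %d of %s",
                   cn, df[[cn]][bad[1]], bad[1] + 1L, path))
    }
    df[[cn]] <- as.integer(v)
  }

  df$mspi <- collapse_strand(df$mspi_fwd, df$mspi_rev)
  if (drop_unassayable) {
    keep <- is_assayable(df$mspi_fwd, df$mspi_rev, min_reads = assayable_min)
    df <- df[keep, , drop = FALSE]
  }
  if (nrow(df) == 0) return(list())

  fwd_m <- as.matrix(df[, sprintf("hpaii_%s_fwd", libs), drop = FALSE])
  rev_m <- as.matrix(df[, sprintf("hpaii_%s_rev", libs), drop = FALSE])
  colnames(fwd_m) <- colnames(rev_m) <- libs
  rownames(fwd_m) <- rownames(rev_m) <- NULL
  coll <- pmax(fwd_m, rev_m)

  idx <- split(seq_len(nrow(df)), factor(df$region_id,
                                         levels = unique(df$region_id)))
  regions <- lapply(names(idx), function(rid) {
    i <- idx[[rid]]
    if (length(unique(df$chrom[i])) != 1) {
      stop(sprintf("region %s spans multiple chromosomes", rid))
    }
    i <- i[order(df$pos[i])]
    sites <- data.frame(site_id = df$site_id[i], pos = df$pos[i],
                        mspi_fwd = df$mspi_fwd[i], mspi_rev = df$mspi_rev[i],
                        mspi = df$mspi[i], stringsAsFactors = FALSE)
    new_region(rid, df$chrom[i][1], sites,
               hpaii = coll[i, , drop = FALSE],
               hpaii_fwd = fwd_m[i, , drop = FALSE],
               hpaii_rev = rev_m[i, , drop = FALSE])
  })
  regions
}

#' Write regions back to the tag-count dialect
#'
#' Inverse of [read_tagcounts()]: writes one row per site with strand-level
#' counts, so reading the written file recovers the surviving rows exactly.
#'
#' @param regions list of `methyl_region` objects.
#' @param path output file path.
#' @export
write_tagcounts <- function(regions, path) {
  stopifnot(length(regions) > 0)
  libs <- colnames(regions[[1]]$hpaii)
  rows <- lapply(regions, function(r) {
    fwd <- if (is.null(r$hpaii_fwd)) r$hpaii else r$hpaii_fwd
    rev <- if (is.null(r$hpaii_rev)) matrix(0L, r$K, length(libs),
                                            dimnames = list(NULL, libs))
           else r$hpaii_rev
    out <- data.frame(chrom = r$chrom, pos = r$sites$pos,
                      region_id = r$region_id, site_id = r$sites$site_id,
                      mspi_fwd = r$sites$mspi_fwd,
                      mspi_rev = r$sites$mspi_rev,
                      stringsAsFactors = FALSE)
    for (lib in libs) {
      out[[sprintf("hpaii_%s_fwd", lib)]] <- fwd[, lib]
      out[[sprintf("hpaii_%s_rev", lib)]] <- rev[, lib]
    }
    out
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Export region spans as BED intervals
#'
#' Converts the 1-based fully-closed site coordinates into 0-based
#' half-open BED intervals covering the first to the last CCGG site of
#' each region (the recognition site is 4 bp, so the interval end is
#' `last pos + 3` in 1-based closed coordinates, i.e. `last pos + 3` in
#' BED's exclusive end).
#'
#' @param regions list of `methyl_region` objects.
#' @param path optional output path; when given, a 4-column BED file is
#'   written.
#' @return data.frame with `chrom`, `start`, `end`, `name`.
#' @export
regions_to_bed <- function(regions, path = NULL) {
  bed <- do.call(rbind, lapply(regions, function(r) {
    data.frame(chrom = r$chrom,
               start = min(r$sites$pos) - 1L,
               end = max(r$sites$pos) + 3L,
               name = r$region_id, stringsAsFactors = FALSE)
  }))
  if (!is.null(path)) {
    write.table(bed, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  bed
}

#' Write / read methylation-estimate tables
#'
#' TSV with columns `region_id`, `library_id`, `method`, `mu`, `variance`
#' (variance is `NA` for non-Bayesian methods).
#'
#' @param estimates data.frame as returned by [estimate_regions()].
#' @param path file path.
#' @export
write_estimates <- function(estimates, path) {
  write.table(estimates, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_estimates
#' @export
read_estimates <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Read a per-library depth-bias table
#'
#' TSV with columns `library_id` and `c` (the HpaII-to-MspI effective
#' sequencing-depth ratio, see [compute_depth_bias()]).
#'
#' @param path file path.
#' @return named numeric vector of bias ratios.
#' @export
read_bias <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("library_id", "c") %in% names(df))) {
    stop("bias file must have columns library_id, c")
  }
  if (any(df$c <= 0)) stop("bias ratios must be positive")
  stats::setNames(df$c, df$library_id)
}
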