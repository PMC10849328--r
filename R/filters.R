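#' Hard-filter thresholds
#'
#' The fixed thresholds of the QC stage. Exclusion is strict at every
#' boundary: a call is masked when `DP < dp_call_min`, `GQ < gq_min`, or
#' `DP >= dp_max_factor x` the sample's mean autosomal depth; a heterozygote
#' additionally when `min(AD) < het_ad_min` or its reference-read fraction
#' falls outside `[het_ad_ratio_range]` (outside, not on, the bounds). A
#' site is dropped when it is an indel, multiallelic, `MQ < mq_min`,
#' `MQ0F > mq0f_max`, at most `indel_dist_min_bp` from an indel, outside the
#' mapability mask, or missing in more than `site_missing_max` of samples.
#' A sample is flagged when more than `sample_missing_max` of its genotypes
#' are missing, or (advisory) when mitochondrial minor-read fractions exceed
#' `mito_contam_af` at more than `mito_contam_site_frac` of sites.
#'
#' @param mq_min,mq0f_max,indel_dist_min_bp,dp_call_min,gq_min,het_ad_min
#'   site- and call-level cutoffs, see above.
#' @param het_ad_ratio_range allowed band for `AD_ref / (AD_ref + AD_alt)`
#'   at heterozygous calls.
#' @param dp_max_factor multiple of the per-sample mean autosomal depth at or
#'   above which a call is masked.
#' @param site_missing_max,sample_missing_max missingness fractions (strict).
#' @param mito_contam_af minor-read fraction above which a mitochondrial
#'   site looks contaminated.
#' @param mito_contam_site_frac fraction of such sites above which the
#'   sample is flagged.
#' @param maf_gwas,min_allele_count frequency-filter defaults used by
#'   [frequency_filters()].
#' @param dp_gq_rule `"or"` (default; either `DP < dp_call_min` or
#'   `GQ < gq_min` masks the call) or `"and"` (both required).
#' @return list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(mq_min = 50.0, mq0f_max = 0.1,
                              indel_dist_min_bp = 3, dp_call_min = 4,
                              gq_min = 30, het_ad_min = 2,
                              het_ad_ratio_range = c(0.25, 0.75),
                              dp_max_factor = 1.65,
                              site_missing_max = 0.20,
                              sample_missing_max = 0.30,
                              mito_contam_af = 0.20,
                              mito_contam_site_frac = 0.05,
                              maf_gwas = 0.05, min_allele_count = 1,
                              dp_gq_rule = c("or", "and")) {
  th <- list(mq_min = mq_min, mq0f_max = mq0f_max,
             indel_dist_min_bp = indel_dist_min_bp,
             dp_call_min = dp_call_min, gq_min = gq_min,
             het_ad_min = het_ad_min,
             het_ad_ratio_range = het_ad_ratio_range,
             dp_max_factor = dp_max_factor,
             site_missing_max = site_missing_max,
             sample_missing_max = sample_missing_max,
             mito_contam_af = mito_contam_af,
             mito_contam_site_frac = mito_contam_site_frac,
             maf_gwas = maf_gwas, min_allele_count = min_allele_count,
             dp_gq_rule = match.arg(dp_gq_rule))
  assert_that(all(vapply(th[1:14], function(x) all(is.finite(x)), TRUE)),
              "all thresholds must be finite")
  assert_that(all(het_ad_ratio_range >= 0 & het_ad_ratio_range <= 1) &&
              het_ad_ratio_range[1] <= het_ad_ratio_range[2],
              "het_ad_ratio_range must be an ordered pair within [0,1]")
  assert_that(dp_max_factor > 0, "dp_max_factor must be positive")
  structure(th, class = "filter_thresholds")
}

.mito_chroms <- c("MT", "chrM", "chrMT", "M", "Mt")

#' Mean autosomal depth per sample
#'
#' Arithmetic mean of `DP` over a sample's called genotypes at autosomal
#' (non-mitochondrial) sites; the reference point of the high-depth filter.
#' Computed on pre-filter calls: depth is a property of the sequencing run,
#' not of site QC.
#'
#' @param calls a [genotype_calls()].
#' @param records matching site annotations (for the chromosome names).
#' @param autosomes optional character vector of chromosomes to use;
#'   defaults to every chromosome not named like a mitochondrial contig.
#' @return named numeric vector, one mean per sample.
#' @export
mean_autosomal_depth <- function(calls, records = NULL, autosomes = NULL) {
  keep <- rep(TRUE, n_variants(calls))
  if (!is.null(records)) {
    keep <- if (is.null(autosomes)) !(records$chrom %in% .mito_chroms)
            else records$chrom %in% autosomes
  }
  dp <- calls$dp[, keep, drop = FALSE]
  dp[is.na(calls$dosage[, keep, drop = FALSE])] <- NA
  ncalled <- rowSums(!is.na(dp))
  bad <- which(ncalled == 0)
  assert_that(length(bad) == 0L,
              paste("sample(s) with zero called autosomal genotypes:",
                    paste(rownames(calls$dosage)[bad], collapse = ", ")))
  rowMeans(dp, na.rm = TRUE)
}

#' Per-genotype hard filters
#'
#' Masks (sets to missing) calls failing the depth, quality and allele-depth
#' rules of [filter_thresholds()]. The two AD rules touch heterozygotes
#' only. The rules are order-independent: each only sets calls missing.
#'
#' @param calls a [genotype_calls()].
#' @param thresholds a [filter_thresholds()].
#' @param mean_depths per-sample mean autosomal depth from
#'   [mean_autosomal_depth()] (computed on the pre-filter calls).
#' @return list with `calls` (masked copy) and `report`, a `filter_report`
#'   holding one logical samples-x-variants mask per reason
#'   (`DP_LOW`, `GQ_LOW`, `DP_HIGH`, `AD_LOW`, `AD_RATIO`) plus counts.
#' @export
apply_genotype_filters <- function(calls, thresholds = filter_thresholds(),
                                   mean_depths = NULL) {
  th <- thresholds
  if (is.null(mean_depths)) mean_depths <- mean_autosomal_depth(calls)
  assert_that(length(mean_depths) == n_samples(calls),
              "need one mean depth per sample")
  called <- !is.na(calls$dosage)
  het <- called & calls$dosage == 1L
  dp_low <- called & !is.na(calls$dp) & calls$dp < th$dp_call_min
  gq_low <- called & !is.na(calls$gq) & calls$gq < th$gq_min
  if (th$dp_gq_rule == "and") {
    both <- dp_low & gq_low
    dp_low <- gq_low <- both
  }
  dp_high <- called & !is.na(calls$dp) &
    calls$dp >= th$dp_max_factor * mean_depths   # recycles down columns
  ad_min <- pmin(calls$ad_ref, calls$ad_alt)
  ad_low <- het & !is.na(ad_min) & ad_min < th$het_ad_min
  tot <- calls$ad_ref + calls$ad_alt
  ratio <- ifelse(!is.na(tot) & tot > 0, calls$ad_ref / tot, NA_real_)
  ad_ratio <- het & !is.na(ratio) &
    (ratio < th$het_ad_ratio_range[1] | ratio > th$het_ad_ratio_range[2])

  reasons <- list(DP_LOW = dp_low, GQ_LOW = gq_low, DP_HIGH = dp_high,
                  AD_LOW = ad_low, AD_RATIO = ad_ratio)
  mask <- Reduce(`|`, reasons)
  out <- calls
  out$dosage[mask] <- NA_integer_
  report <- structure(list(
    level = "genotype",
    reasons = reasons,
    counts = vapply(reasons, sum, 0L),
    n_masked = sum(mask)), class = "filter_report")
  list(calls = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report (%s level):\n", x$level))
  for (r in names(x$counts))
    cat(sprintf("  %-12s %d\n", r, x$counts[[r]]))
  invisible(x)
}

#' Read a BED mapability mask
#'
#' BED intervals are 0-based half-open; they are converted to 1-based
#' inclusive coordinates on import (the one place the conversion happens).
#' Intervals must be sorted and non-overlapping within chromosome.
#'
#' @param path BED file of retained (mappable) regions.
#' @return a `GRanges` of retained regions.
#' @export
read_bed_mask <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  check_mask(gr)
}

check_mask <- function(gr) {
  for (ch in as.character(unique(GenomicRanges::seqnames(gr)))) {
    g <- gr[as.character(GenomicRanges::seqnames(gr)) == ch]
    s <- GenomicRanges::start(g); e <- GenomicRanges::end(g)
    assert_that(all(diff(s) > 0) && all(s[-1] > e[-length(e)]),
                sprintf("mask intervals on %s are unsorted or overlapping", ch))
  }
  gr
}

site_in_mask <- function(records, mask) {
  sites <- GenomicRanges::GRanges(records$chrom,
                                  IRanges::IRanges(records$pos, records$pos))
  GenomicRanges::countOverlaps(sites, mask) > 0
}

#' Per-site hard filters
#'
#' Drops indels, multiallelic sites, low mapping quality (`MQ`, `MQ0F`),
#' sites within `indel_dist_min_bp` of an indel, sites outside the
#' mapability mask, and sites whose post-genotype-filter missingness exceeds
#' `site_missing_max` (strictly).
#'
#' @param records site annotations (with `is_indel`, `is_multiallelic`,
#'   `mq`, `mq0f`, `indel_distance`).
#' @param calls genotype calls *after* [apply_genotype_filters()], used for
#'   the missingness rule.
#' @param mask `NULL`, a `GRanges` of retained regions, or a BED path.
#' @param thresholds a [filter_thresholds()].
#' @return list with `keep` (logical per site), `report` (`filter_report`
#'   with per-site reason masks `INDEL`, `MULTIALLELIC`, `MQ`, `MQ0F`,
#'   `NEAR_INDEL`, `MASKED`, `MISSINGNESS` and counts).
#' @export
apply_site_filters <- function(records, calls, mask = NULL,
                               thresholds = filter_thresholds()) {
  th <- thresholds
  assert_that(nrow(records) == n_variants(calls),
              "records and calls disagree on the number of sites")
  if (is.character(mask)) mask <- read_bed_mask(mask)
  if (!is.null(mask)) check_mask(mask)
  miss_frac <- colMeans(is.na(calls$dosage))
  reasons <- list(
    INDEL = records$is_indel,
    MULTIALLELIC = records$is_multiallelic,
    MQ = !is.na(records$mq) & records$mq < th$mq_min,
    MQ0F = !is.na(records$mq0f) & records$mq0f > th$mq0f_max,
    NEAR_INDEL = !records$is_indel &
      records$indel_distance <= th$indel_dist_min_bp,
    MASKED = if (is.null(mask)) rep(FALSE, nrow(records))
             else !site_in_mask(records, mask),
    MISSINGNESS = miss_frac > th$site_missing_max)
  drop <- Reduce(`|`, reasons)
  report <- structure(list(level = "site", reasons = reasons,
                           counts = vapply(reasons, sum, 0L),
                           n_masked = sum(drop)), class = "filter_report")
  list(keep = !drop, report = report)
}

#' Per-sample QC verdicts
#'
#' `HIGH_MISSING` when more than `sample_missing_max` of a sample's
#' genotypes are missing after all site and genotype filters.
#' `CONTAM_FLAG` (advisory, never auto-dropping) when, across mitochondrial
#' sites, the fraction of sites whose minor-read fraction exceeds
#' `mito_contam_af` is above `mito_contam_site_frac`.
#'
#' @param calls post-filter autosomal [genotype_calls()] restricted to kept
#'   sites.
#' @param thresholds a [filter_thresholds()].
#' @param mito_calls optional [genotype_calls()] of mitochondrial sites
#'   (pre-filter; read evidence is what matters), or `NULL` to skip the
#'   contamination check.
#' @return data.frame: `sample_id`, `missing_frac`, `verdict`
#'   (`KEPT`/`HIGH_MISSING`), `contam_frac`, `contam_flag`.
#' @export
sample_qc <- function(calls, thresholds = filter_thresholds(),
                      mito_calls = NULL) {
  th <- thresholds
  miss <- rowMeans(is.na(calls$dosage))
  out <- data.frame(
    sample_id = rownames(calls$dosage) %||% paste0("S", seq_len(n_samples(calls))),
    missing_frac = miss,
    verdict = ifelse(miss > th$sample_missing_max, "HIGH_MISSING", "KEPT"),
    contam_frac = NA_real_, contam_flag = FALSE,
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(mito_calls)) {
    dp <- mito_calls$dp
    minor <- pmin(mito_calls$ad_ref, mito_calls$ad_alt) / ifelse(dp > 0, dp, NA)
    hit <- minor > th$mito_contam_af
    out$contam_frac <- rowMeans(hit, na.rm = TRUE)
    out$contam_flag <- !is.na(out$contam_frac) &
      out$contam_frac > th$mito_contam_site_frac
  }
  out
}

#' Frequency filters (MAC / MAF) over non-missing alleles
#'
#' Minor-allele frequency and count are computed from the called alleles of
#' the included samples only. `maf` keeps sites with `MAF >= maf_gwas`
#' (inclusive); `mac` keeps sites whose minor allele is seen at least
#' `min_allele_count` times. Sites with zero called alleles are dropped.
#'
#' @param calls a [genotype_calls()].
#' @param mode `"maf"` or `"mac"`.
#' @param samples optional sample subset (ids, logical or indices).
#' @param thresholds a [filter_thresholds()] supplying `maf_gwas` and
#'   `min_allele_count`.
#' @return logical keep vector over sites.
#' @export
frequency_filters <- function(calls, mode = c("maf", "mac"), samples = NULL,
                              thresholds = filter_thresholds()) {
  mode <- match.arg(mode)
  ac <- allele_counts(calls, samples)
  minor <- pmin(ac$a, ac$n - ac$a)
  keep <- ac$n > 0
  out <- if (mode == "maf") keep & (minor / pmax(ac$n, 1) >= thresholds$maf_gwas)
         else keep & (minor >= thresholds$min_allele_count)
  unname(out)
}
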