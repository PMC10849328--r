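#' Container for diploid genotype calls
#'
#' Holds a samples-by-variants dosage matrix (counts of the alternate allele,
#' `NA` = missing call) together with the per-call sequencing evidence the
#' hard filters consume: total depth `DP`, per-allele depths `AD` and the
#' phred-scaled genotype quality `GQ`.
#'
#' @param dosage integer matrix, samples x variants, values in `0:2` or `NA`.
#' @param dp,ad_ref,ad_alt,gq integer matrices of the same shape; `NA` where
#'   no call was emitted.
#' @return An object of class `genotype_calls` (a named list of the five
#'   matrices).
#' @export
genotype_calls <- function(dosage, dp, ad_ref, ad_alt, gq) {
  mats <- list(dosage = dosage, dp = dp, ad_ref = ad_ref,
               ad_alt = ad_alt, gq = gq)
  dims <- vapply(mats, function(m) paste(dim(m), collapse = "x"), "")
  assert_that(length(unique(dims)) == 1L,
              "all genotype_calls matrices must share the same dimensions")
  bad <- which(!is.na(dosage) & !(dosage %in% 0:2))
  assert_that(length(bad) == 0L, "dosage values must be 0, 1, 2 or NA")
  ok <- !is.na(ad_ref) & !is.na(ad_alt) & !is.na(dp)
  assert_that(all(ad_ref[ok] + ad_alt[ok] <= dp[ok]),
              "AD_ref + AD_alt must never exceed DP")
  structure(mats, class = "genotype_calls")
}

#' @export
print.genotype_calls <- function(x, ...) {
  cat(sprintf("genotype_calls: %d samples x %d variants (%.1f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @rdname genotype_calls
#' @param x a `genotype_calls` object.
#' @export
n_samples <- function(x) nrow(x$dosage)

#' @rdname genotype_calls
#' @export
n_variants <- function(x) ncol(x$dosage)

#' Subset a genotype_calls object
#'
#' @param x a `genotype_calls` object.
#' @param samples sample ids, logical mask or integer indices (rows).
#' @param variants logical mask or integer indices (columns).
#' @return A `genotype_calls` object restricted to the selection.
#' @export
subset_calls <- function(x, samples = NULL, variants = NULL) {
  i <- resolve_samples(x, samples)
  j <- if (is.null(variants)) seq_len(n_variants(x)) else variants
  out <- lapply(unclass(x), function(m) m[i, j, drop = FALSE])
  structure(out, class = "genotype_calls")
}

# Map a sample selector (NULL, ids, logical, integer) to row indices.
resolve_samples <- function(x, samples) {
  if (is.null(samples)) return(seq_len(n_samples(x)))
  if (is.character(samples)) {
    idx <- match(samples, rownames(x$dosage))
    assert_that(!anyNA(idx), paste("unknown sample id(s):",
                paste(samples[is.na(idx)], collapse = ", ")))
    return(idx)
  }
  if (is.logical(samples)) return(which(samples))
  samples
}
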