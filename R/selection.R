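#' Missingness-aware allele counts
#'
#' @param calls a [genotype_calls()].
#' @param samples optional subset (ids, logical or indices).
#' @return list with `n` (called allele total, 2 per non-missing genotype)
#'   and `a` (alternate-allele count), one entry per site.
#' @export
allele_counts <- function(calls, samples = NULL) {
  d <- calls$dosage[resolve_samples(calls, samples), , drop = FALSE]
  list(n = 2L * colSums(!is.na(d)),
       a = colSums(d, na.rm = TRUE))
}

#' Variant-count window specification
#'
#' @param size_variants window size in variants.
#' @param step_variants step between window starts, `<= size_variants`.
#' @return list of class `window_spec`.
#' @export
window_spec <- function(size_variants, step_variants) {
  assert_that(size_variants >= 1 && step_variants >= 1,
              "window size and step must be >= 1")
  assert_that(step_variants <= size_variants, "step must not exceed size")
  structure(list(size_variants = as.integer(size_variants),
                 step_variants = as.integer(step_variants)),
            class = "window_spec")
}

# Window start/end indices (1-based inclusive) over n sites. Full windows
# advance by `step`; one trailing short window is appended when sites remain
# and include_partial is TRUE.
make_windows <- function(n, spec, include_partial = TRUE) {
  size <- spec$size_variants; step <- spec$step_variants
  if (n < size) {
    if (!include_partial) return(data.frame(start = integer(0),
                                            end = integer(0),
                                            partial = logical(0)))
    return(data.frame(start = 1L, end = n, partial = TRUE))
  }
  starts <- seq.int(1L, n - size + 1L, by = step)
  w <- data.frame(start = starts, end = starts + size - 1L, partial = FALSE)
  last <- w$end[nrow(w)]
  if (include_partial && last < n) {
    s <- w$start[nrow(w)] + step
    w <- rbind(w, data.frame(start = s, end = n, partial = TRUE))
  }
  w
}

# Per-site Hudson numerator/denominator. A site contributes only when both
# populations have >= 2 called alleles.
hudson_site_components <- function(countsA, countsB) {
  n1 <- countsA$n; a1 <- countsA$a
  n2 <- countsB$n; a2 <- countsB$a
  valid <- n1 >= 2 & n2 >= 2
  p1 <- ifelse(valid, a1 / n1, NA_real_)
  p2 <- ifelse(valid, a2 / n2, NA_real_)
  N <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  D <- p1 * (1 - p2) + p2 * (1 - p1)
  list(N = N, D = D, valid = valid)
}

windowed_frame <- function(w, records, n_used, value) {
  data.frame(
    chrom = if (is.null(records)) NA_character_ else records$chrom[w$start],
    start_idx = w$start - 1L, end_idx = w$end - 1L,
    start_bp = if (is.null(records)) NA_real_ else records$pos[w$start],
    end_bp = if (is.null(records)) NA_real_ else records$pos[w$end],
    n_variants_used = n_used, partial = w$partial, value = value,
    stringsAsFactors = FALSE)
}

#' Windowed Hudson FST (ratio of averages)
#'
#' Per site, with `p_i = a_i / n_i`:
#' `N = (p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and
#' `D = p1(1-p2) + p2(1-p1)`; a window's FST is `sum(N)/sum(D)` over its
#' contributing sites (Hudson's estimator in ratio-of-averages form).
#' Negative values are small-sample behaviour and are reported as-is. A
#' window whose denominator sum is zero gets `NA`, never a silent 0.
#'
#' @param countsA,countsB per-population [allele_counts()].
#' @param window a [window_spec()].
#' @param records optional site annotations for bp coordinates.
#' @param include_partial emit the trailing short window (flagged)?
#' @return data.frame of windows: `chrom`, variant-index span (0-based
#'   inclusive), bp span, `n_variants_used`, `partial`, `value`.
#' @export
hudson_fst_window <- function(countsA, countsB, window, records = NULL,
                              include_partial = TRUE) {
  hc <- hudson_site_components(countsA, countsB)
  w <- make_windows(length(countsA$n), window, include_partial)
  sums <- window_ratio_sums(hc, w)
  windowed_frame(w, records, sums$n_used, sums$value)
}

window_ratio_sums <- function(hc, w) {
  value <- numeric(nrow(w)); n_used <- integer(nrow(w))
  for (i in seq_len(nrow(w))) {
    j <- w$start[i]:w$end[i]
    use <- hc$valid[j]
    n_used[i] <- sum(use)
    D <- sum(hc$D[j][use]); N <- sum(hc$N[j][use])
    value[i] <- if (n_used[i] == 0 || D == 0) NA_real_ else N / D
  }
  list(value = value, n_used = n_used)
}

#' Windowed population branch statistic
#'
#' For each window the three pairwise Hudson FST values are transformed to
#' branch lengths `T = -ln(1 - FST)` (FST clipped just below 1 before the
#' log; negative FST passes through unclipped) and combined as
#' `PBS = (T_f,c1 + T_f,c2 - T_c1,c2) / 2`: the allele-frequency branch
#' specific to the focal population since its split from the contrasts.
#'
#' @param counts_focal,counts_c1,counts_c2 [allele_counts()] of the focal
#'   population and the two contrasts.
#' @inheritParams hudson_fst_window
#' @param eps clipping margin below 1 for the log transform.
#' @return data.frame of windows with the three pairwise FST values, branch
#'   lengths and `value` (the PBS).
#' @export
pbs_windows <- function(counts_focal, counts_c1, counts_c2, window,
                        records = NULL, include_partial = TRUE,
                        eps = 1e-6) {
  w <- make_windows(length(counts_focal$n), window, include_partial)
  pair <- function(a, b) window_ratio_sums(hudson_site_components(a, b), w)
  f1 <- pair(counts_focal, counts_c1)
  f2 <- pair(counts_focal, counts_c2)
  f3 <- pair(counts_c1, counts_c2)
  branch <- function(fst) -log(1 - pmin(fst, 1 - eps))
  t1 <- branch(f1$value); t2 <- branch(f2$value); t3 <- branch(f3$value)
  out <- windowed_frame(w, records, pmin(f1$n_used, f2$n_used, f3$n_used),
                        (t1 + t2 - t3) / 2)
  out$fst_focal_c1 <- f1$value; out$fst_focal_c2 <- f2$value
  out$fst_c1_c2 <- f3$value
  out$t_focal_c1 <- t1; out$t_focal_c2 <- t2; out$t_c1_c2 <- t3
  out
}

#' Windowed observed heterozygosity
#'
#' Fraction of called genotypes that are heterozygous, pooled over all
#' samples and sites of each window.
#'
#' @param calls a [genotype_calls()].
#' @param samples optional sample subset.
#' @param expected use expected heterozygosity `2*p*(1-p)` averaged over the
#'   window's sites (frequency from the subset's called alleles) instead of
#'   the observed het fraction.
#' @inheritParams hudson_fst_window
#' @return data.frame of windows as in [hudson_fst_window()].
#' @export
windowed_heterozygosity <- function(calls, samples = NULL, window,
                                    records = NULL, include_partial = TRUE,
                                    expected = FALSE) {
  d <- calls$dosage[resolve_samples(calls, samples), , drop = FALSE]
  w <- make_windows(ncol(d), window, include_partial)
  value <- numeric(nrow(w)); n_used <- integer(nrow(w))
  if (expected) {
    ac <- list(n = 2L * colSums(!is.na(d)), a = colSums(d, na.rm = TRUE))
    p <- ifelse(ac$n > 0, ac$a / ac$n, NA_real_)
    h <- 2 * p * (1 - p)
  }
  for (i in seq_len(nrow(w))) {
    j <- w$start[i]:w$end[i]
    if (expected) {
      use <- !is.na(h[j])
      n_used[i] <- sum(use)
      value[i] <- if (n_used[i]) mean(h[j][use]) else NA_real_
    } else {
      dj <- d[, j, drop = FALSE]
      ncall <- sum(!is.na(dj))
      n_used[i] <- sum(colSums(!is.na(dj)) > 0)
      value[i] <- if (ncall == 0) NA_real_ else sum(dj == 1L, na.rm = TRUE) / ncall
    }
  }
  windowed_frame(w, records, n_used, value)
}

#' Invariant-site-aware nucleotide diversity (ratio of sums)
#'
#' Per site the number of pairwise differences among called alleles is
#' `diffs = n_ref * n_alt` and the number of comparisons `comps =
#' choose(n_called, 2)`; invariant sites contribute `diffs = 0` with their
#' full `comps`. The regional estimate is `pi = sum(diffs) / sum(comps)` —
#' the ratio-of-sums estimator that stays unbiased under missing data
#' because uncalled genotypes shrink numerator and denominator together.
#' Sites with fewer than 2 called alleles contribute nothing.
#'
#' @param calls a [genotype_calls()] that includes invariant sites.
#' @param records matching site annotations.
#' @param samples optional sample subset.
#' @param region `NULL` (all sites), a `"chrom:start-end"` string, or a list
#'   with `chrom`, `start`, `end` (1-based inclusive bp).
#' @return list with `pi`, `n_sites` (contributing), `diffs`, `comps` and
#'   `per_site` (data.frame of the per-site pieces). `pi` is `NA` when no
#'   site contributes.
#' @export
pi_invariant_aware <- function(calls, records, samples = NULL, region = NULL) {
  keep <- rep(TRUE, nrow(records))
  if (!is.null(region)) {
    r <- parse_region(region)
    keep <- records$chrom == r$chrom & records$pos >= r$start &
            records$pos <= r$end
  }
  assert_that(any(keep), "region contains no sites")
  d <- calls$dosage[resolve_samples(calls, samples), keep, drop = FALSE]
  n <- 2L * colSums(!is.na(d))
  a <- colSums(d, na.rm = TRUE)
  diffs <- a * (n - a)
  comps <- n * (n - 1) / 2
  use <- n >= 2
  per_site <- data.frame(chrom = records$chrom[keep], pos = records$pos[keep],
                         n_alleles = n, n_alt = a,
                         diffs = ifelse(use, diffs, 0),
                         comps = ifelse(use, comps, 0))
  tot_c <- sum(per_site$comps)
  list(pi = if (tot_c == 0) NA_real_ else sum(per_site$diffs) / tot_c,
       n_sites = sum(use), diffs = sum(per_site$diffs), comps = tot_c,
       per_site = per_site)
}

parse_region <- function(region) {
  if (is.list(region)) return(region)
  m <- regmatches(region, regexec("^([^:]+):([0-9.eE+]+)-([0-9.eE+]+)$", region))[[1]]
  assert_that(length(m) == 4, "region must look like chrom:start-end")
  list(chrom = m[2], start = as.numeric(m[3]), end = as.numeric(m[4]))
}
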