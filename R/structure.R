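#' LD-pruning specification
#'
#' @param window_bp sliding window width in bp.
#' @param step_bp step between window starts, `<= window_bp`.
#' @param r2_threshold prune one of each pair with `r^2` strictly above
#'   this (0.2 for the PCA set; 0.1 is the stricter admixture-style value).
#' @return list of class `prune_spec`.
#' @export
prune_spec <- function(window_bp = 50000, step_bp = 10000,
                       r2_threshold = 0.2) {
  assert_that(step_bp <= window_bp, "step must not exceed window")
  assert_that(r2_threshold > 0 && r2_threshold <= 1,
              "r2_threshold must be in (0,1]")
  structure(list(window_bp = window_bp, step_bp = step_bp,
                 r2_threshold = r2_threshold), class = "prune_spec")
}

#' Greedy windowed LD pruning
#'
#' Slides bp windows along each chromosome; within a window, pairs of
#' surviving variants are examined in position order and whenever their
#' `r^2` exceeds the threshold the variant with the lower minor-allele
#' frequency is dropped (ties drop the later position). The result is
#' deterministic and guarantees that no surviving pair within any window
#' exceeds the threshold.
#'
#' @param calls a [genotype_calls()].
#' @param records position-sorted site annotations.
#' @param spec a [prune_spec()].
#' @param variants optional site subset (indices) to prune within.
#' @return integer vector of kept variant indices (into the full records).
#' @export
ld_prune <- function(calls, records, spec = prune_spec(), variants = NULL) {
  idx <- variants %||% seq_len(nrow(records))
  check_sorted_records(records[idx, , drop = FALSE])
  d <- calls$dosage[, idx, drop = FALSE]
  ac <- allele_counts(calls)
  maf <- with(ac, ifelse(n > 0, pmin(a, n - a) / pmax(n, 1), 0))[idx]
  keep <- rep(TRUE, length(idx))
  for (ch in unique(records$chrom[idx])) {
    on_ch <- which(records$chrom[idx] == ch)
    pos <- records$pos[idx][on_ch]
    starts <- seq(min(pos), max(pos), by = spec$step_bp)
    for (s in starts) {
      inw <- on_ch[pos >= s & pos < s + spec$window_bp]
      inw <- inw[keep[inw]]
      if (length(inw) < 2) next
      for (ii in seq_len(length(inw) - 1)) {
        i <- inw[ii]
        if (!keep[i]) next
        for (jj in seq((ii + 1), length(inw))) {
          j <- inw[jj]
          if (!keep[j]) next
          r2 <- suppressWarnings(tryCatch(ld_r2(d[, i], d[, j]),
                                          error = function(e) NA_real_))
          if (!is.na(r2) && r2 > spec$r2_threshold) {
            # drop the lower-MAF variant; tie -> later position
            drop <- if (maf[i] < maf[j]) i else if (maf[j] < maf[i]) j else j
            keep[drop] <- FALSE
            if (drop == i) break
          }
        }
      }
    }
  }
  idx[keep]
}

#' Principal component analysis of genotypes
#'
#' Missing dosages are imputed to the variant mean; each variant is centred
#' by `2*p` and scaled by `sqrt(2*p*(1-p))` (`p` the sample alternate-allele
#' frequency); the samples-by-samples covariance is eigendecomposed and
#' coordinates are eigenvectors scaled by the square roots of their
#' eigenvalues. Monomorphic variants are excluded. The sign of each
#' component is fixed so its largest-magnitude coordinate is positive.
#'
#' @param calls a [genotype_calls()].
#' @param variants optional site subset (e.g. an [ld_prune()] result).
#' @param n_components number of components to return.
#' @return list of class `genotype_pca`: `scores` (samples x components),
#'   `eigenvalues` (all, non-increasing), `n_variants_used`.
#' @export
pca_genotypes <- function(calls, variants = NULL, n_components = 10) {
  d <- if (is.null(variants)) calls$dosage else
    calls$dosage[, variants, drop = FALSE]
  assert_that(nrow(d) >= 2, "need at least two samples")
  p <- colMeans(d, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  assert_that(sum(poly) >= n_components,
              "fewer polymorphic variants than requested components")
  d <- d[, poly, drop = FALSE]; p <- p[poly]
  x <- sweep(d, 2, 2 * p, `-`)
  x[is.na(x)] <- 0                     # mean imputation after centring
  x <- sweep(x, 2, sqrt(2 * p * (1 - p)), `/`)
  cov <- tcrossprod(x) / ncol(x)
  e <- eigen(cov, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  k <- seq_len(n_components)
  scores <- e$vectors[, k, drop = FALSE] %*% diag(sqrt(vals[k]), length(k))
  for (j in k) {
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) scores[, j] <- -scores[, j]
  }
  dimnames(scores) <- list(rownames(d), paste0("PC", k))
  structure(list(scores = scores, eigenvalues = vals,
                 n_variants_used = ncol(x)), class = "genotype_pca")
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Two-sided p by summing hypergeometric probabilities no larger than that
#' of the observed table. A zero margin yields `p = 1` with a warning.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return the two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  tab <- as.matrix(table)
  assert_that(all(dim(tab) == c(2, 2)) && all(tab >= 0),
              "need a 2x2 table of non-negative counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero margin: p = 1 by convention", call. = FALSE)
    return(1)
  }
  fisher.test(tab)$p.value
}

#' Mann-Whitney U test with midranks
#'
#' `U` comes from rank sums with midranks for ties. The two-sided p-value
#' is exact — from the full permutation distribution of the rank sum,
#' computed by dynamic programming (equivalent to enumerating all
#' allocations) — when `nA * nB <= exact_max`; otherwise a normal
#' approximation with tie correction (no continuity correction) is used.
#'
#' @param x,y numeric samples for the two groups.
#' @param exact_max switch to the normal approximation above this product
#'   of group sizes.
#' @return list with `U` (for the first group), two-sided `p`, and
#'   `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney_u <- function(x, y, exact_max = 400) {
  nA <- length(x); nB <- length(y)
  assert_that(nA >= 1 && nB >= 1, "both groups must be non-empty")
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nA)])
  U <- W - nA * (nA + 1) / 2
  N <- nA + nB
  if (length(unique(c(x, y))) == 1L)
    return(list(U = U, p = 1, method = "degenerate"))
  if (nA * nB <= exact_max) {
    r2 <- as.integer(round(2 * r))          # doubled midranks are integers
    dist <- ranksum_distribution(r2, nA)
    mu2 <- nA * (N + 1)                     # mean of the doubled rank sum
    w2 <- as.integer(round(2 * W))
    sums <- as.numeric(names(dist))
    p <- sum(dist[abs(sums - mu2) >= abs(w2 - mu2) - 1e-9]) / sum(dist)
    return(list(U = U, p = p, method = "exact"))
  }
  mu <- nA * nB / 2
  ties <- table(r)
  sigma2 <- nA * nB / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- (U - mu) / sqrt(sigma2)
  list(U = U, p = min(1, 2 * pnorm(-abs(z))), method = "normal")
}

# Number of ways to pick nA of the doubled ranks with each possible sum:
# the exact permutation distribution of the rank sum (counts, named by sum).
ranksum_distribution <- function(r2, nA) {
  smax <- sum(sort(r2, decreasing = TRUE)[seq_len(nA)])
  f <- matrix(0, nA + 1, smax + 1)
  f[1, 1] <- 1
  for (r in r2) {
    kmax <- nA
    for (k in kmax:1) {
      src <- f[k, 1:(smax + 1 - r)]
      if (any(src != 0))
        f[k + 1, (r + 1):(smax + 1)] <- f[k + 1, (r + 1):(smax + 1)] + src
    }
  }
  counts <- f[nA + 1, ]
  names(counts) <- 0:smax
  counts[counts > 0]
}

#' @importFrom stats pnorm
NULL

#' Compare ancestry proportions between gamecocks and nongame chickens
#'
#' Applies the Mann-Whitney U contrast to one component of an externally
#' produced ancestry-proportion table (samples x components; this package
#' does not fit admixture models itself).
#'
#' @param q data.frame with a `sample_id` column and one column per
#'   ancestry component.
#' @param samples sample sheet (`sample_id`, `group`).
#' @param component name of the component column to compare.
#' @return list with `U`, `p`, `method` and the two group medians.
#' @export
compare_ancestry <- function(q, samples, component) {
  assert_that(component %in% names(q),
              sprintf("component '%s' not in ancestry table", component))
  m <- merge(samples, q, by = "sample_id")
  a <- m[[component]][m$group == "gamecock"]
  b <- m[[component]][m$group == "nongame"]
  assert_that(length(a) > 0 && length(b) > 0,
              "need both gamecocks and nongame samples in the table")
  res <- mann_whitney_u(a, b)
  c(res, list(median_gamecock = median(a), median_nongame = median(b)))
}
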