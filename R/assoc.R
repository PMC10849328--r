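#' Pairwise identity-by-state distance
#'
#' Over the sites at which both samples are called, the per-site IBS share
#' is `1 - |dosage_i - dosage_j| / 2` (1 for identical genotypes, 1/2 for a
#' het vs a homozygote, 0 for opposite homozygotes); the distance is one
#' minus the mean share.
#'
#' @param calls a [genotype_calls()].
#' @param samples optional sample subset.
#' @param variants optional site subset.
#' @return symmetric distance matrix with zero diagonal, values in `[0,1]`.
#' @export
ibs_distance <- function(calls, samples = NULL, variants = NULL) {
  d <- subset_calls(calls, samples, variants)$dosage
  assert_that(nrow(d) >= 2, "need at least two samples")
  called <- !is.na(d)
  storage.mode(called) <- "double"
  co <- tcrossprod(called)                      # co-called site counts
  ind <- lapply(0:2, function(v) {
    m <- !is.na(d) & d == v; storage.mode(m) <- "double"; m
  })
  # sum over co-called sites of |d_i - d_j|
  s01 <- tcrossprod(ind[[1]], ind[[2]]); s12 <- tcrossprod(ind[[2]], ind[[3]])
  s02 <- tcrossprod(ind[[1]], ind[[3]])
  absdiff <- s01 + t(s01) + s12 + t(s12) + 2 * (s02 + t(s02))
  off <- co == 0 & row(co) != col(co)
  if (any(off)) {
    ij <- which(off, arr.ind = TRUE)[1, ]
    stop_(sprintf("samples %s and %s share no co-called site",
                  rownames(d)[ij[1]], rownames(d)[ij[2]]))
  }
  dist <- absdiff / (2 * co)
  diag(dist) <- 0
  dimnames(dist) <- list(rownames(d), rownames(d))
  dist
}

#' Complete-linkage clustering of samples
#'
#' Standard agglomerative clustering (merge criterion: maximum intra-cluster
#' distance) cut at `K` clusters; deterministic for a given distance matrix.
#'
#' @param dist symmetric distance matrix (e.g. [ibs_distance()]).
#' @param K number of clusters, `1 <= K <= n`.
#' @return list of class `cluster_partition`: `K`, `assignment` (named
#'   integer vector, cluster ids `1..K`) and the underlying `hclust` tree.
#' @export
complete_linkage <- function(dist, K) {
  n <- nrow(dist)
  assert_that(K >= 1 && K <= n, "K must be between 1 and the sample count")
  hc <- hclust(as.dist(dist), method = "complete")
  structure(list(K = as.integer(K), assignment = cutree(hc, k = K),
                 hclust = hc), class = "cluster_partition")
}

#' Samples in phenotype-informative strata
#'
#' Only strata containing both cases and controls contribute to the CMH
#' statistic; this counts the samples sitting in such strata (the "samples
#' in clusters" used to break ties between K values).
#'
#' @param assignment integer cluster ids per sample.
#' @param case logical case indicator per sample.
#' @return integer count.
#' @export
informative_samples <- function(assignment, case) {
  sum(unlist(lapply(split(case, assignment), function(x)
    if (any(x) && any(!x)) length(x) else 0L)))
}

# Per-stratum allele-count margins for every variant: a (case alt alleles),
# n1 (case called alleles), m1 (alt alleles) and tt (called alleles), each a
# K x V matrix.
cmh_margins <- function(calls, case, assignment, variants = NULL) {
  d <- if (is.null(variants)) calls$dosage else
    calls$dosage[, variants, drop = FALSE]
  ks <- sort(unique(assignment))
  K <- length(ks); V <- ncol(d)
  a <- n1 <- m1 <- tt <- matrix(0, K, V)
  for (i in seq_along(ks)) {
    rows <- which(assignment == ks[i])
    dk <- d[rows, , drop = FALSE]
    ck <- case[rows]
    a[i, ] <- colSums(dk[ck, , drop = FALSE], na.rm = TRUE)
    n1[i, ] <- 2 * colSums(!is.na(dk[ck, , drop = FALSE]))
    m1[i, ] <- colSums(dk, na.rm = TRUE)
    tt[i, ] <- 2 * colSums(!is.na(dk))
  }
  list(a = a, n1 = n1, m1 = m1, tt = tt)
}

# Core CMH chi-square from margin matrices (strata x variants).
cmh_core <- function(a, n1, m1, tt) {
  w <- tt > 1
  E <- ifelse(w, n1 * m1 / tt, 0)
  Vk <- ifelse(w, n1 * (tt - n1) * m1 * (tt - m1) / (tt^2 * (tt - 1)), 0)
  num <- colSums(ifelse(w, a, 0) - E)
  den <- colSums(Vk)
  chi2 <- ifelse(den > 0, num^2 / den, NA_real_)
  data.frame(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Cochran-Mantel-Haenszel test on stratified allele-count tables
#'
#' One-degree-of-freedom CMH chi-square,
#' `chi2 = (sum_k (a_k - E_k))^2 / sum_k V_k` with
#' `E_k = n1k m1k / T_k` and `V_k = n1k n2k m1k m2k / (T_k^2 (T_k - 1))`,
#' no continuity correction. Strata with `T_k <= 1` or a zero margin
#' contribute nothing; if no stratum contributes the statistic is `NA`
#' (reported, never 0). With a single stratum this equals the Pearson
#' chi-square times the exact finite-sample factor `(N-1)/N`.
#'
#' @param tables a `2 x 2 x K` array for one variant (rows case/control,
#'   columns alt/ref allele counts), or a list of such arrays (one per
#'   variant).
#' @return data.frame with `chi2` and upper-tail `p` per variant.
#' @export
cmh_test <- function(tables) {
  if (is.array(tables) && length(dim(tables)) == 3) tables <- list(tables)
  stats <- lapply(tables, function(tab) {
    a <- tab[1, 1, ]; n1 <- tab[1, 1, ] + tab[1, 2, ]
    m1 <- tab[1, 1, ] + tab[2, 1, ]; tt <- apply(tab, 3, sum)
    cmh_core(matrix(a, ncol = 1), matrix(n1, ncol = 1),
             matrix(m1, ncol = 1), matrix(tt, ncol = 1))
  })
  do.call(rbind, stats)
}

#' Stratified association scan over all variants
#'
#' Builds per-stratum allele-count tables (cases = gamecocks by default) and
#' runs the CMH test at every variant.
#'
#' @param calls a [genotype_calls()].
#' @param case logical per-sample case indicator.
#' @param partition a [complete_linkage()] partition (or a bare assignment
#'   vector).
#' @param variants optional site subset.
#' @return data.frame with `chi2` and `p` per variant.
#' @export
assoc_cmh <- function(calls, case, partition, variants = NULL) {
  assignment <- if (inherits(partition, "cluster_partition"))
    partition$assignment else partition
  m <- cmh_margins(calls, case, assignment, variants)
  cmh_core(m$a, m$n1, m$m1, m$tt)
}

#' Genomic control
#'
#' The inflation factor is the median observed chi-square divided by the
#' median of the 1-df chi-square distribution (0.4549...), floored at 1 so
#' the correction never deflates; statistics are divided by lambda and
#' p-values recomputed from the 1-df upper tail.
#'
#' @param chi2 vector of association chi-squares (NA allowed).
#' @return list with `lambda`, `chi2_adj` and `p_adj`.
#' @export
genomic_control <- function(chi2) {
  assert_that(length(chi2) >= 1 && any(is.finite(chi2)),
              "need at least one finite chi-square")
  lambda <- max(1, median(chi2, na.rm = TRUE) / qchisq(0.5, df = 1))
  chi2_adj <- chi2 / lambda
  list(lambda = lambda, chi2_adj = chi2_adj,
       p_adj = pchisq(chi2_adj, df = 1, lower.tail = FALSE))
}

#' Choose the number of strata by genomic inflation
#'
#' For each candidate `K`: cluster the samples (complete linkage on IBS
#' distance), run the CMH scan and compute lambda. The chosen `K` minimises
#' lambda; ties are broken by the larger number of samples in informative
#' strata, remaining ties by the smaller `K`. A `K` at which no stratum is
#' informative has undefined lambda and is excluded.
#'
#' @param calls a [genotype_calls()].
#' @param case logical case indicator.
#' @param k_range integer vector of candidate K values (>= 2 candidates).
#' @param dist optional precomputed distance matrix (saves recomputation).
#' @param variants optional site subset used for the scans.
#' @return list with `best_k`, `table` (K, lambda, informative_samples) and
#'   `partition` (the winning [complete_linkage()] partition).
#' @export
select_k <- function(calls, case, k_range, dist = NULL, variants = NULL) {
  assert_that(length(k_range) >= 2, "need at least two candidate K values")
  if (is.null(dist)) dist <- ibs_distance(calls)
  rows <- lapply(k_range, function(K) {
    part <- complete_linkage(dist, K)
    res <- assoc_cmh(calls, case, part, variants)
    lam <- if (all(!is.finite(res$chi2))) NA_real_
           else genomic_control(res$chi2)$lambda
    list(K = K, lambda = lam,
         informative = informative_samples(part$assignment, case),
         partition = part)
  })
  tab <- data.frame(K = vapply(rows, `[[`, 0, "K"),
                    lambda = vapply(rows, `[[`, 0, "lambda"),
                    informative_samples = vapply(rows, `[[`, 0L, "informative"))
  best <- pick_best_k(tab)
  list(best_k = tab$K[best], table = tab, partition = rows[[best]]$partition)
}

# Tie-break rule: min lambda, then max informative samples, then min K.
pick_best_k <- function(tab) {
  ok <- which(is.finite(tab$lambda))
  assert_that(length(ok) > 0, "lambda undefined at every candidate K")
  ord <- ok[order(tab$lambda[ok], -tab$informative_samples[ok], tab$K[ok])]
  ord[1]
}

#' Within-cluster permutation p-values
#'
#' Phenotype labels are shuffled independently within each stratum,
#' preserving per-stratum case counts, and the CMH chi-square recomputed for
#' every variant. The pointwise p-value uses the add-one estimator
#' `p = (1 + #\{perm >= observed\}) / (1 + n_perm)` (never exactly zero; the
#' smallest attainable value with 10,000 permutations is `1/10001`, which
#' passes the `p < 1e-4` significance threshold).
#'
#' @param calls a [genotype_calls()].
#' @param case logical case indicator.
#' @param partition a [complete_linkage()] partition or assignment vector.
#' @param n_perm number of permutations (default 10,000).
#' @param seed integer seed; identical seeds give identical p-values.
#' @param variants optional site subset.
#' @param alpha significance threshold on the permutation p.
#' @param chunk_size permutations processed per block (memory knob).
#' @return data.frame per variant: `chi2` (observed), `p_perm`,
#'   `significant` (`p_perm < alpha`).
#' @export
permutation_p <- function(calls, case, partition, n_perm = 10000L,
                          seed = 1L, variants = NULL, alpha = 1e-4,
                          chunk_size = 2000L) {
  assert_that(n_perm >= 1, "n_perm must be >= 1")
  assignment <- if (inherits(partition, "cluster_partition"))
    partition$assignment else partition
  d <- if (is.null(variants)) calls$dosage else
    calls$dosage[, variants, drop = FALSE]
  V <- ncol(d)
  ks <- sort(unique(assignment))
  strata <- lapply(ks, function(k) {
    rows <- which(assignment == k)
    dk <- d[rows, , drop = FALSE]
    d0 <- dk; d0[is.na(d0)] <- 0
    called <- !is.na(dk); storage.mode(called) <- "double"
    m1 <- colSums(d0); tt <- 2 * colSums(called)
    w <- as.numeric(tt > 1)
    list(n = length(rows), n_case = sum(case[rows]), d0 = d0,
         called = called, m1 = m1 * w, tt = tt,
         # per-variant fixed factors of E_k and V_k
         e_fac = ifelse(tt > 1, m1 / tt, 0),
         v_fac = ifelse(tt > 1, m1 * (tt - m1) / (tt^2 * (tt - 1)), 0),
         w = w)
  })
  obs <- assoc_cmh(calls, case, assignment, variants)

  exceed <- numeric(V)
  withr::with_seed(seed, {
    done <- 0L
    while (done < n_perm) {
      B <- min(chunk_size, n_perm - done)
      num <- matrix(0, B, V); den <- matrix(0, B, V)
      for (st in strata) {
        ind <- matrix(0, B, st$n)
        if (st$n_case > 0)
          for (b in seq_len(B))
            ind[b, sample.int(st$n, st$n_case)] <- 1
        A <- sweep(ind %*% st$d0, 2, st$w, `*`)
        N1 <- 2 * (ind %*% st$called)
        num <- num + A - sweep(N1, 2, st$e_fac, `*`)
        den <- den + sweep(N1 * sweep(-N1, 2, st$tt, `+`), 2, st$v_fac, `*`)
      }
      chi2p <- ifelse(den > 0, num^2 / den, NA_real_)
      # ">= observed" with a relative tolerance so that a permutation that
      # reproduces an equivalent labelling counts as a tie despite round-off;
      # an undefined permuted statistic counts as exceeding (conservative)
      thr <- obs$chi2 - pmax(abs(obs$chi2), 1) * 1e-9
      cmp <- sweep(chi2p, 2, thr, `>=`) | is.na(chi2p)
      exceed <- exceed + colSums(cmp)
      done <- done + B
    }
  })
  p <- (1 + exceed) / (1 + n_perm)
  p[!is.finite(obs$chi2)] <- NA_real_
  data.frame(chi2 = obs$chi2, p_perm = p,
             significant = !is.na(p) & p < alpha)
}

#' Composite genotypic LD
#'
#' Squared Pearson correlation of two dosage vectors over co-called samples.
#'
#' @param dosages_i,dosages_j dosage vectors (`0/1/2/NA`).
#' @return `r^2`, or `NA` (with a warning) when either vector is
#'   monomorphic among the co-called samples.
#' @export
ld_r2 <- function(dosages_i, dosages_j) {
  ok <- !is.na(dosages_i) & !is.na(dosages_j)
  assert_that(sum(ok) >= 2, "need at least two co-called samples")
  x <- dosages_i[ok]; y <- dosages_j[ok]
  if (var(x) == 0 || var(y) == 0) {
    warning("monomorphic input: r^2 undefined", call. = FALSE)
    return(NA_real_)
  }
  cor(x, y)^2
}

#' Per-group alternate-allele frequencies
#'
#' @param calls a [genotype_calls()].
#' @param samples data.frame aligned with the calls' rows (needs
#'   `sample_id` and the grouping column).
#' @param by grouping column name (default `"group"`).
#' @return matrix, sites x groups; `NA` where a group has no called allele.
#' @export
group_allele_frequencies <- function(calls, samples, by = "group") {
  groups <- unique(samples[[by]])
  assert_that(length(groups) >= 1, "no groups found")
  out <- sapply(groups, function(g) {
    ac <- allele_counts(calls, samples[[by]] == g)
    ifelse(ac$n > 0, ac$a / ac$n, NA_real_)
  })
  out <- matrix(out, ncol = length(groups),
                dimnames = list(colnames(calls$dosage), groups))
  out
}
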