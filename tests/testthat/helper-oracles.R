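# Independent brute-force oracles. Everything here counts allele pairs or
# enumerates configurations directly; nothing shares code with R/.

# Hudson FST for one window, via literal pair counting:
# within-pop heterozygosity  = differing allele pairs / all pairs,
# between-pop heterozygosity = differing cross-pop pairs / all cross pairs,
# window FST = 1 - sum(Hw)/sum(Hb) over sites where both pops have >= 2 alleles.
o_fst_window <- function(nA, aA, nB, aB, from, to) {
  hw <- hb <- 0
  for (s in from:to) {
    if (nA[s] < 2 || nB[s] < 2) next
    hwA <- aA[s] * (nA[s] - aA[s]) / (nA[s] * (nA[s] - 1) / 2)
    hwB <- aB[s] * (nB[s] - aB[s]) / (nB[s] * (nB[s] - 1) / 2)
    hb_s <- (aA[s] * (nB[s] - aB[s]) + aB[s] * (nA[s] - aA[s])) / (nA[s] * nB[s])
    hw <- hw + (hwA + hwB) / 2
    hb <- hb + hb_s
  }
  if (hb == 0) return(NA_real_)
  1 - hw / hb
}

o_pbs <- function(fst1, fst2, fst3, eps = 1e-6) {
  tr <- function(f) -log(1 - min(f, 1 - eps))
  (tr(fst1) + tr(fst2) - tr(fst3)) / 2
}

# Observed heterozygosity of a dosage block, by explicit loop.
o_het <- function(d) {
  nhet <- 0; ncall <- 0
  for (i in seq_len(nrow(d))) for (j in seq_len(ncol(d))) {
    if (is.na(d[i, j])) next
    ncall <- ncall + 1
    if (d[i, j] == 1) nhet <- nhet + 1
  }
  if (ncall == 0) NA_real_ else nhet / ncall
}

# pi by enumerating every pair of called alleles at every site.
o_pi <- function(d) {
  diffs <- 0; comps <- 0
  for (j in seq_len(ncol(d))) {
    alleles <- c()
    for (i in seq_len(nrow(d))) {
      if (is.na(d[i, j])) next
      alleles <- c(alleles, c(0, 0, 1)[d[i, j] + 1], c(0, 1, 1)[d[i, j] + 1])
    }
    n <- length(alleles)
    if (n < 2) next
    for (x in 1:(n - 1)) for (y in (x + 1):n) {
      comps <- comps + 1
      if (alleles[x] != alleles[y]) diffs <- diffs + 1
    }
  }
  if (comps == 0) NA_real_ else diffs / comps
}

# CMH chi-square for one variant from a list of 2x2 stratum tables
# (rows case/control, columns alt/ref), scalar arithmetic.
o_cmh <- function(tabs) {
  num <- 0; den <- 0
  for (tab in tabs) {
    tt <- sum(tab)
    if (tt <= 1) next
    a <- tab[1, 1]; n1 <- sum(tab[1, ]); m1 <- sum(tab[, 1])
    num <- num + a - n1 * m1 / tt
    den <- den + n1 * (tt - n1) * m1 * (tt - m1) / (tt^2 * (tt - 1))
  }
  if (den == 0) return(NA_real_)
  num^2 / den
}

# Fisher two-sided p by summing hypergeometric point probabilities that do
# not exceed the observed table's.
o_fisher <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Mann-Whitney exact two-sided p by full enumeration of allocations,
# two-sidedness as distance of the rank sum from its mean.
o_mwu <- function(x, y) {
  nA <- length(x); N <- nA + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nA)])
  mu <- nA * (N + 1) / 2
  combos <- utils::combn(N, nA)
  ws <- apply(combos, 2, function(idx) sum(r[idx]))
  list(U = w_obs - nA * (nA + 1) / 2,
       p = mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9))
}

# Complete-linkage criterion of a partition: the largest intra-cluster
# distance (for brute-force checks of small clusterings).
o_max_intra <- function(dist, assignment) {
  worst <- 0
  for (k in unique(assignment)) {
    idx <- which(assignment == k)
    if (length(idx) >= 2)
      worst <- max(worst, max(dist[idx, idx]))
  }
  worst
}
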