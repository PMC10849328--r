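test_that("IBS distance counts shared alleles over co-called sites", {
  d <- rbind(a = c(0L, 2L), b = c(0L, 2L), c = c(2L, 0L), e = c(0L, 0L))
  dist <- ibs_distance(make_calls(d))
  expect_equal(unname(dist["a", "b"]), 0)
  expect_equal(unname(dist["a", "c"]), 1)      # opposite homozygotes everywhere
  expect_equal(unname(dist["a", "e"]), 0.5)    # shares (1, 0) per site
  expect_true(isSymmetric(dist))
  expect_true(all(diag(dist) == 0))

  no_overlap <- make_calls(rbind(c(0L, NA), c(NA, 0L)))
  expect_error(ibs_distance(no_overlap), "no co-called site")
})

test_that("complete linkage is exact at the trivial cuts and on a brute-forced 4-point metric", {
  withr::with_seed(5, {
    d <- matrix(runif(36, 0.2, 1), 6, 6); d <- (d + t(d)) / 2; diag(d) <- 0
  })
  expect_equal(unname(complete_linkage(d, 6)$assignment), 1:6)
  expect_equal(unique(complete_linkage(d, 1)$assignment), 1L)

  # two tight pairs far apart: the unique optimal 2-partition
  p4 <- matrix(c(0, .05, .9, .95,  .05, 0, .92, .88,
                 .9, .92, 0, .04,  .95, .88, .04, 0), 4, 4)
  got <- complete_linkage(p4, 2)$assignment
  expect_equal(got[1], got[2])
  expect_equal(got[3], got[4])
  expect_false(got[1] == got[3])
  # brute force: no other 2-partition has a smaller maximum intra distance
  best <- min(vapply(1:7, function(m) {
    asg <- as.integer(intToBits(m))[1:4] + 1L
    if (length(unique(asg)) != 2) return(Inf)
    o_max_intra(p4, asg)
  }, 0))
  expect_equal(o_max_intra(p4, got), best)
})

test_that("CMH equals (N-1)/N times Pearson for one stratum and the scalar oracle for several", {
  withr::with_seed(6, {
    for (i in 1:100) {
      tab <- matrix(rpois(4, 12) + 1, 2, 2)
      got <- cmh_test(array(tab, c(2, 2, 1)))
      pearson <- suppressWarnings(
        chisq.test(tab, correct = FALSE)$statistic)
      N <- sum(tab)
      expect_equal(got$chi2, unname(pearson) * (N - 1) / N, tolerance = 1e-10)
    }
    for (i in 1:25) {
      K <- sample(2:4, 1)
      tabs <- lapply(seq_len(K), function(k) matrix(rpois(4, 10) + 1, 2, 2))
      arr <- array(unlist(tabs), c(2, 2, K))
      got <- cmh_test(arr)$chi2
      expect_equal(got, o_cmh(tabs), tolerance = 1e-10)
      mh <- mantelhaen.test(aperm(arr, c(2, 1, 3)), correct = FALSE)
      expect_equal(got, unname(mh$statistic), tolerance = 1e-8)
    }
  })
})

test_that("CMH is zero when cases equal controls, NA when nothing contributes, and allele-label invariant", {
  eq <- array(matrix(c(5, 5, 7, 7), 2, 2), c(2, 2, 2))
  expect_equal(cmh_test(eq)$chi2, 0)

  empty <- array(matrix(c(1, 0, 0, 0), 2, 2), c(2, 2, 1))   # zero margins
  expect_true(is.na(cmh_test(empty)$chi2))

  withr::with_seed(8, tab <- matrix(rpois(4, 9) + 1, 2, 2))
  swapped <- tab[, 2:1]
  expect_equal(cmh_test(array(tab, c(2, 2, 1)))$chi2,
               cmh_test(array(swapped, c(2, 2, 1)))$chi2, tolerance = 1e-12)
})

test_that("genomic control floors lambda at 1 and recovers a known inflation scale", {
  flat <- genomic_control(rep(qchisq(0.5, 1), 5))
  expect_equal(flat$lambda, 1)
  expect_equal(flat$chi2_adj, rep(qchisq(0.5, 1), 5))

  withr::with_seed(9, deflated <- 0.5 * rchisq(1e5, 1))
  expect_equal(genomic_control(deflated)$lambda, 1)

  withr::with_seed(10, inflated <- 2.61 * rchisq(1e6, 1))
  expect_equal(genomic_control(inflated)$lambda, 2.61, tolerance = 0.02 / 2.61)
})

test_that("K selection minimises lambda with informative-sample and smaller-K tie-breaks", {
  tab <- data.frame(K = 2:5, lambda = c(2.0, 1.2, 1.2, 1.2),
                    informative_samples = c(100, 90, 110, 110))
  expect_equal(tab$K[gamescan:::pick_best_k(tab)], 4)   # lambda tie -> larger
                                                        # informative; then smaller K
  tab$lambda[1] <- NA
  expect_equal(tab$K[gamescan:::pick_best_k(tab)], 4)
  expect_error(gamescan:::pick_best_k(
    data.frame(K = 1:2, lambda = NA_real_, informative_samples = 0)),
    "undefined")

  expect_equal(informative_samples(c(1, 1, 2, 2), c(TRUE, FALSE, TRUE, TRUE)),
               2L)
})

test_that("stratification removes confounding inflation on the default cohort", {
  co <- simulate_cohort(sim_config(seed = 2))
  case <- co$samples$group == "gamecock"
  maf <- which(frequency_filters(co$calls, "maf") & !co$records$is_invariant)
  pruned <- ld_prune(co$calls, co$records, prune_spec(), maf)
  sel <- select_k(co$calls, case, 1:4,
                  ibs_distance(co$calls, variants = pruned), maf)
  lam <- sel$table$lambda
  expect_gt(lam[1], 1.5)            # unstratified scan is visibly inflated
  expect_lt(lam[2], lam[1])         # two strata absorb the region confounder
  expect_gt(sel$best_k, 1)
})

test_that("null cohorts give lambda near 1 at every K", {
  co <- simulate_cohort(null_cohort_config(3, n_variants = 5000L,
                                           n_samples = 110L))
  case <- null_case(3, 110, n_case = 48)
  maf <- which(frequency_filters(co$calls, "maf"))
  dist <- ibs_distance(co$calls, variants = maf)
  for (K in 1:4) {
    part <- if (K == 1) rep(1L, 110) else complete_linkage(dist, K)$assignment
    lam <- genomic_control(assoc_cmh(co$calls, case, part, maf)$chi2)$lambda
    expect_gte(lam, 0.9); expect_lte(lam, 1.1)
  }
})

test_that("permutation p is seeded, bounded below by 1/(n_perm+1), and rank-concordant with analytic p", {
  co <- simulate_cohort(null_cohort_config(12, n_variants = 300L,
                                           n_samples = 110L))
  case <- null_case(12, 110, n_case = 48)
  maf <- which(frequency_filters(co$calls, "maf"))
  part <- complete_linkage(ibs_distance(co$calls, variants = maf), 2)
  p1 <- permutation_p(co$calls, case, part, n_perm = 10000, seed = 7,
                      variants = maf)
  p2 <- permutation_p(co$calls, case, part, n_perm = 10000, seed = 7,
                      variants = maf)
  expect_identical(p1, p2)
  expect_true(all(p1$p_perm >= 1 / 10001, na.rm = TRUE))
  expect_lt(1 / 10001, 1e-4)   # the 10,000-permutation floor passes p < 1e-4

  analytic <- assoc_cmh(co$calls, case, part, maf)$p
  ok <- !is.na(p1$p_perm) & !is.na(analytic)
  expect_gt(cor(p1$p_perm[ok], analytic[ok], method = "spearman"), 0.99)
})

test_that("LD r^2 handles perfect correlation, independence, and degenerate input", {
  expect_equal(ld_r2(c(0, 1, 2, 0), c(0, 1, 2, 0)), 1)
  expect_equal(ld_r2(c(0, 1, 2, 0), c(2, 1, 0, 2)), 1)
  withr::with_seed(14, {
    x <- rbinom(1000, 2, 0.4); y <- rbinom(1000, 2, 0.4)
  })
  expect_lt(ld_r2(x, y), 0.01)
  expect_warning(r <- ld_r2(c(1, 1, 1), c(0, 1, 2)), "monomorphic")
  expect_true(is.na(r))
})

test_that("group allele frequencies are missingness-aware", {
  # 48 gamecocks with 86 alt alleles of 96: 38 hom alt + 10 het
  dosage <- matrix(c(rep(2L, 38), rep(1L, 10), rep(0L, 62)), ncol = 1)
  samples <- data.frame(sample_id = paste0("s", 1:110),
                        group = rep(c("gamecock", "nongame"), c(48, 62)))
  rownames(dosage) <- samples$sample_id
  f <- group_allele_frequencies(make_calls(dosage), samples)
  expect_equal(unname(f[1, "gamecock"]), 86 / 96)
  expect_equal(unname(round(100 * f[1, "gamecock"], 1)), 89.6)
  expect_equal(unname(f[1, "nongame"]), 0)

  dosage[1:48, 1] <- NA   # no called gamecock allele -> undefined
  f2 <- group_allele_frequencies(make_calls(dosage), samples)
  expect_true(is.na(f2[1, "gamecock"]))
})
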