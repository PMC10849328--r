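test_that("mean autosomal depth averages called genotypes and skips mito sites", {
  calls <- make_calls(rbind(c(0L, 1L, 2L)), dp = rbind(c(10L, 20L, 30L)))
  expect_equal(unname(mean_autosomal_depth(calls)), 20)

  calls2 <- make_calls(rbind(c(0L, NA, 2L)), dp = rbind(c(10L, 99L, 30L)))
  expect_equal(unname(mean_autosomal_depth(calls2)), 20)

  rec <- make_records(c(5, 10, 15), chrom = c("chr1", "chrM", "chr1"))
  calls3 <- make_calls(rbind(c(0L, 0L, 0L)), dp = rbind(c(10L, 500L, 30L)))
  expect_equal(unname(mean_autosomal_depth(calls3, rec)), 20)

  empty <- make_calls(rbind(c(NA_integer_, NA_integer_)))
  expect_error(mean_autosomal_depth(empty), "S1")
})

test_that("per-sample mean depth on a simulated cohort matches the Poisson mean", {
  co <- simulate_cohort(sim_config(n_variants = 400L, n_invariant_sites = 0L,
                                   mean_depth = 12, seed = 13))
  md <- mean_autosomal_depth(co$calls, co$records)
  se3 <- 3 * sqrt(12 / 380)    # >= 380 called sites per sample
  expect_true(all(abs(md - 12) < se3 + 0.2))
})

test_that("genotype filters mask exactly the calls the rules describe", {
  # one sample, five calls: AD_RATIO het, boundary hom kept, AD_LOW het,
  # DP_LOW, GQ_LOW
  dosage <- rbind(c(1L, 0L, 1L, 1L, 2L))
  dp     <- rbind(c(12L, 4L, 8L, 3L, 30L))
  ad_alt <- rbind(c(10L, 0L, 7L, 1L, 30L))
  ad_ref <- dp - ad_alt
  gq     <- rbind(c(50L, 30L, 40L, 60L, 29L))
  calls <- make_calls(dosage, dp, ad_ref, ad_alt, gq)
  out <- apply_genotype_filters(calls, filter_thresholds(),
                                mean_depths = 100)
  expect_equal(unname(out$calls$dosage[1, ]), c(NA, 0L, NA, NA, NA))
  expect_true(out$report$reasons$AD_RATIO[1, 1])   # 2/12 < 0.25
  expect_true(out$report$reasons$AD_LOW[1, 3])     # min AD 1 < 2
  expect_true(out$report$reasons$DP_LOW[1, 4])
  expect_true(out$report$reasons$GQ_LOW[1, 5])
  expect_equal(sum(out$report$reasons$DP_HIGH), 0L)
})

test_that("high-depth exclusion uses each sample's own mean and includes the boundary", {
  dosage <- rbind(c(0L, 0L), c(0L, 0L))
  dp <- rbind(c(33L, 32L),    # mean depth 20 -> 1.65x = 33: 33 masked, 32 kept
              c(33L, 33L))    # mean depth 40 -> both kept
  calls <- make_calls(dosage, dp)
  out <- apply_genotype_filters(calls, filter_thresholds(),
                                mean_depths = c(20, 40))
  expect_equal(unname(out$calls$dosage[1, ]), c(NA, 0L))
  expect_equal(unname(out$calls$dosage[2, ]), c(0L, 0L))
})

test_that("the two AD rules never touch homozygous calls and filtering is idempotent", {
  dosage <- rbind(c(0L, 2L, 1L))
  dp <- rbind(c(12L, 12L, 12L))
  ad_alt <- rbind(c(1L, 11L, 6L))   # homs have error reads; het balanced
  calls <- make_calls(dosage, dp, dp - ad_alt, ad_alt)
  once <- apply_genotype_filters(calls, mean_depths = 12 / 1.65 + 1)
  expect_equal(once$calls$dosage, calls$dosage)
  twice <- apply_genotype_filters(once$calls, mean_depths = 12 / 1.65 + 1)
  expect_identical(twice$calls$dosage, once$calls$dosage)
})

test_that("site filters drop by missingness with a strict boundary", {
  dosage <- matrix(0L, 10, 2)
  dosage[1:3, 1] <- NA   # 30% missing -> dropped
  dosage[1:2, 2] <- NA   # exactly 20% -> kept
  calls <- make_calls(dosage)
  rec <- make_records(c(100, 200))
  sf <- apply_site_filters(rec, calls)
  expect_equal(sf$keep, c(FALSE, TRUE))
  expect_true(sf$report$reasons$MISSINGNESS[1])
})

test_that("site filters apply MQ, MQ0F, indel and near-indel rules as stated", {
  rec <- make_records(c(10, 20, 30, 40, 50, 60),
                      mq = c(50, 49.9, 60, 60, 60, 60),
                      mq0f = c(0.1, 0, 0.11, 0, 0, 0))
  rec$is_indel[4] <- TRUE
  rec$indel_distance <- c(Inf, Inf, Inf, 0, 3, 4)
  calls <- make_calls(matrix(1L, 4, 6))
  sf <- apply_site_filters(rec, calls)
  # MQ=50 kept; MQ<50 dropped; MQ0F>0.1 dropped; indel dropped;
  # distance 3 dropped (must be strictly > 3), distance 4 kept
  expect_equal(sf$keep, c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_true(sf$report$reasons$MQ[2])
  expect_true(sf$report$reasons$MQ0F[3])
  expect_true(sf$report$reasons$INDEL[4])
  expect_true(sf$report$reasons$NEAR_INDEL[5])
})

test_that("the BED mask is 0-based half-open against 1-based positions", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chrS\t0\t100", bed)
  rec <- make_records(c(100, 101))
  calls <- make_calls(matrix(1L, 4, 2))
  sf <- apply_site_filters(rec, calls, mask = bed)
  expect_equal(sf$keep, c(TRUE, FALSE))   # mask covers pos 1..100

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chrS\t0\t100", "chrS\t50\t150"), bad)
  expect_error(apply_site_filters(rec, calls, mask = bad), "overlapping")
})

test_that("sample QC flags high missingness strictly and contamination as advisory", {
  dosage <- matrix(0L, 2, 100)
  dosage[1, 1:31] <- NA
  dosage[2, 1:30] <- NA
  qc <- sample_qc(make_calls(dosage))
  expect_equal(qc$verdict, c("HIGH_MISSING", "KEPT"))

  # mito evidence: minor-read fraction 0.5 at 10 of 100 sites -> 10% > 5%
  mito_dp <- matrix(100L, 2, 100)
  ad_alt <- matrix(0L, 2, 100); ad_alt[1, 1:10] <- 50L
  mito <- make_calls(matrix(0L, 2, 100), mito_dp, mito_dp - ad_alt, ad_alt)
  qc2 <- sample_qc(make_calls(matrix(0L, 2, 100)), mito_calls = mito)
  expect_equal(qc2$contam_flag, c(TRUE, FALSE))
  expect_equal(qc2$verdict, c("KEPT", "KEPT"))   # advisory, never auto-drop
})

test_that("frequency filters are inclusive at their boundaries and missingness-aware", {
  dosage <- matrix(0L, 110, 3)
  dosage[1:11, 1] <- 1L            # MAF exactly 11/220 = 0.05 -> kept
  dosage[1:10, 2] <- 1L            # MAF 10/220 < 0.05 -> dropped
  # site 3 monomorphic -> dropped under mac
  calls <- make_calls(dosage)
  expect_equal(frequency_filters(calls, "maf"), c(TRUE, FALSE, FALSE))
  expect_equal(frequency_filters(calls, "mac"), c(TRUE, TRUE, FALSE))

  # kept-site count under maf matches a brute-force recount on a cohort
  co <- simulate_cohort(sim_config(n_variants = 300L, n_invariant_sites = 0L,
                                   seed = 17))
  keep <- frequency_filters(co$calls, "maf")
  recount <- vapply(seq_len(ncol(co$calls$dosage)), function(j) {
    x <- co$calls$dosage[, j]; x <- x[!is.na(x)]
    n <- 2 * length(x); a <- sum(x)
    n > 0 && min(a, n - a) / n >= 0.05
  }, TRUE)
  expect_equal(keep, recount)
})

test_that("raising the site missingness ceiling never drops more sites", {
  co <- simulate_cohort(sim_config(n_variants = 200L, n_invariant_sites = 0L,
                                   missing_rate = 0.15, seed = 19))
  kept <- vapply(c(0.1, 0.2, 0.3, 0.5), function(mx) {
    sum(apply_site_filters(co$records, co$calls,
                           thresholds = filter_thresholds(site_missing_max = mx))$keep)
  }, 0L)
  expect_true(all(diff(kept) >= 0))
})

test_that("a clean high-depth cohort passes the null sanity check", {
  co <- simulate_cohort(sim_config(n_variants = 200L, n_invariant_sites = 0L,
                                   missing_rate = 0, mean_depth = 100,
                                   seed = 23))
  gf <- apply_genotype_filters(co$calls,
                               mean_depths = mean_autosomal_depth(co$calls))
  expect_equal(gf$report$n_masked, 0L)
  sf <- apply_site_filters(co$records, gf$calls)
  # only mapping-quality annotations may exclude sites here
  expect_equal(sum(sf$report$reasons$MISSINGNESS), 0L)
  expect_equal(sum(sf$report$reasons$INDEL), 0L)
  expect_equal(sum(sf$report$reasons$NEAR_INDEL), 0L)
  expect_equal(unname(which(!sf$keep)),
               which(co$records$mq < 50 | co$records$mq0f > 0.1))
})
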