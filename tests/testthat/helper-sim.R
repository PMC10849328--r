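# Shared fixture builders. All data is generated in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small genotype_calls from a dosage matrix, with benign DP/AD/GQ defaults
# unless overridden.
make_calls <- function(dosage, dp = NULL, ad_ref = NULL, ad_alt = NULL,
                       gq = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(dp)) dp <- matrix(20L, nrow(dosage), ncol(dosage))
  if (is.null(ad_alt)) {
    ad_alt <- dp
    ad_alt[] <- as.integer(round(dp * ifelse(is.na(dosage), 0, dosage) / 2))
  }
  if (is.null(ad_ref)) ad_ref <- dp - ad_alt
  if (is.null(gq)) gq <- matrix(60L, nrow(dosage), ncol(dosage))
  storage.mode(dp) <- "integer"; storage.mode(ad_ref) <- "integer"
  storage.mode(ad_alt) <- "integer"; storage.mode(gq) <- "integer"
  na <- is.na(dosage)
  dp[na] <- NA_integer_; ad_ref[na] <- NA_integer_
  ad_alt[na] <- NA_integer_; gq[na] <- NA_integer_
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("S", seq_len(nrow(dosage)))
  dimnames(dp) <- dimnames(ad_ref) <- dimnames(ad_alt) <- dimnames(gq) <-
    dimnames(dosage)
  genotype_calls(dosage, dp, ad_ref, ad_alt, gq)
}

# Minimal site annotations for n SNP records on one chromosome.
make_records <- function(pos, chrom = "chrS", alt = NULL, mq = 60,
                         mq0f = 0, is_indel = FALSE, ref = NULL) {
  n <- length(pos)
  data.frame(chrom = chrom, pos = pos,
             ref = ref %||% rep("A", n),
             alt = alt %||% rep("T", n),
             mq = rep(mq, length.out = n), mq0f = rep(mq0f, length.out = n),
             is_indel = rep(is_indel, length.out = n),
             is_multiallelic = FALSE,
             indel_distance = Inf,
             is_invariant = (alt %||% rep("T", n)) == ".",
             stringsAsFactors = FALSE)
}

# A single panmictic population with no selected locus: the null cohort.
null_cohort_config <- function(seed, n_variants = 500L, n_samples = 60L,
                               missing_rate = 0.03) {
  sim_config(
    n_variants = n_variants, n_invariant_sites = 0L,
    populations = data.frame(label = "pool", group = "nongame",
                             n_samples = as.integer(n_samples),
                             drift_F = 0, region = NA_character_),
    regions = NULL, selected_locus = NULL, haplotype_block_bp = 0,
    missing_rate = missing_rate, seed = seed)
}

# Random phenotype for a null cohort (half cases by default).
null_case <- function(seed, n, n_case = floor(n / 2)) {
  withr::with_seed(seed, sample(c(rep(TRUE, n_case), rep(FALSE, n - n_case))))
}

# One run of the default study-condition cohort plus the variant sets and
# block span the recovery checks need.
recovery_run <- function(seed) {
  co <- simulate_cohort(sim_config(seed = seed))
  mac <- which(frequency_filters(co$calls, "mac") & !co$records$is_invariant)
  maf <- which(frequency_filters(co$calls, "maf") & !co$records$is_invariant)
  blk <- range(co$records$pos[c(co$locus_index, co$block_index)])
  list(co = co, mac = mac, maf = maf, block = blk,
       case = co$samples$group == "gamecock")
}
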