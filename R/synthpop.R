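#' Draw per-population allele frequencies under the drift model
#'
#' Frequencies follow a (hierarchical) Balding-Nichols model: an ancestral
#' frequency `p` per variant is drawn from `Beta(a, b)`; a population at
#' drift `F > 0` then draws its frequency from
#' `Beta(p (1-F)/F, (1-p)(1-F)/F)`, which has mean `p` and variance
#' `F p (1-p)`. `F = 0` copies the upstream frequency exactly. When regions
#' are configured the drift is applied twice: ancestral -> region ->
#' population. The selected locus, if configured, is forced to the
#' gamecock/nongame frequencies in populations of those groups.
#'
#' @param cfg a [sim_config()].
#' @param ancestral optional numeric vector of ancestral frequencies (length
#'   `n_variants`) overriding the Beta draw; used for calibration checks.
#' @return list of class `sim_frequencies`: `freq` (variants x populations
#'   matrix), `positions` (bp of each variant), `invariant_positions`,
#'   `ancestral`, `locus_index` (into `positions`, or `NA`), `block_index`,
#'   `block_r` (copying probability per block variant) and `game_hap` (the
#'   founder haplotype's allele at each block variant).
#' @export
simulate_frequencies <- function(cfg, ancestral = NULL) {
  validate_sim_config(cfg)
  withr::with_seed(cfg$seed, sim_frequencies_impl(cfg, ancestral))
}

# Balding-Nichols draw around upstream frequencies p at drift F.
bn_drift <- function(p, F) {
  if (F <= 0) return(p)
  rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
}

# Site positions: uniform without replacement; the selected locus position is
# always among the variant positions.
sim_site_positions <- function(cfg) {
  L <- cfg$chrom_length_bp
  nv <- cfg$n_variants
  ni <- cfg$n_invariant_sites
  locus <- if (is.null(cfg$selected_locus)) NULL else cfg$selected_locus$pos
  need <- nv + ni - length(locus)
  pos <- sample.int(L, min(L, need + length(locus)))
  pos <- setdiff(pos, locus)[seq_len(need)]
  v <- sort(c(locus, pos[seq_len(nv - length(locus))]))
  inv <- sort(pos[setdiff(seq_len(need), seq_len(nv - length(locus)))])
  list(variant_pos = v, invariant_pos = inv,
       locus_index = if (is.null(locus)) NA_integer_ else match(locus, v))
}

sim_frequencies_impl <- function(cfg, ancestral = NULL) {
  sites <- sim_site_positions(cfg)
  nv <- cfg$n_variants
  anc <- ancestral %||%
    rbeta(nv, cfg$ancestral_freq_beta[1], cfg$ancestral_freq_beta[2])
  anc <- pmin(pmax(anc, 1e-4), 1 - 1e-4)

  region_freq <- list()
  if (!is.null(cfg$regions))
    for (i in seq_len(nrow(cfg$regions)))
      region_freq[[cfg$regions$label[i]]] <-
        bn_drift(anc, cfg$regions$drift_F[i])

  pops <- cfg$populations
  freq <- matrix(NA_real_, nv, nrow(pops),
                 dimnames = list(NULL, pops$label))
  for (i in seq_len(nrow(pops))) {
    base <- anc
    if ("region" %in% names(pops) && !is.null(cfg$regions) &&
        !is.na(pops$region[i]) && pops$region[i] %in% names(region_freq))
      base <- region_freq[[pops$region[i]]]
    freq[, i] <- bn_drift(base, pops$drift_F[i])
  }

  block_index <- integer(0); block_r <- numeric(0); game_hap <- integer(0)
  if (!is.na(sites$locus_index)) {
    sl <- cfg$selected_locus
    freq[sites$locus_index, pops$group == "gamecock"] <- sl$freq_gamecock
    freq[sites$locus_index, pops$group == "nongame"] <- sl$freq_nongame
    if (cfg$haplotype_block_bp > 0) {
      d <- abs(sites$variant_pos - sl$pos)
      block_index <- setdiff(which(d <= cfg$haplotype_block_bp / 2),
                             sites$locus_index)
      block_r <- 1 - 2 * d[block_index] / cfg$haplotype_block_bp
      game_hap <- rbinom(length(block_index), 1L, anc[block_index])
    }
  }
  structure(list(freq = freq, positions = sites$variant_pos,
                 invariant_positions = sites$invariant_pos,
                 ancestral = anc, locus_index = sites$locus_index,
                 block_index = block_index, block_r = block_r,
                 game_hap = game_hap),
            class = "sim_frequencies")
}

#' Simulate a diploid cohort with realistic call-level evidence
#'
#' Genotypes are drawn binomially from the population frequencies of
#' [simulate_frequencies()]. At the selected locus and its haplotype block
#' the two haplotypes of each individual are simulated explicitly: a
#' haplotype carrying the game allele copies a single founder haplotype at
#' each block variant with probability decaying linearly to 0 at the block
#' edge, producing a sweep-like footprint (LD with the locus, reduced
#' diversity in gamecocks). Per-call depth is Poisson, heterozygote allele
#' depths are `Binomial(DP, 1/2)`, homozygotes carry a small number of
#' error reads of the other allele, `GQ = min(99, gq_per_depth * DP)`, and
#' calls are masked missing at `missing_rate`. Identical configurations
#' (including the seed) give bit-identical output.
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_cohort` with elements `samples` (data.frame
#'   `sample_id`, `group`, `population`), `records` (data.frame of site
#'   annotations, sorted by position; invariant sites have `alt == "."`),
#'   `calls` (a [genotype_calls()]), `frequencies` (the `sim_frequencies`
#'   object), `locus_index`/`block_index` (row indices into `records`) and
#'   `config`.
#' @export
simulate_cohort <- function(cfg) {
  validate_sim_config(cfg)
  pops <- cfg$populations
  if (!is.null(cfg$selected_locus)) {
    assert_that(any(pops$group == "gamecock") && any(pops$group == "nongame"),
      "a selected locus needs at least one gamecock and one nongame population")
  }
  withr::with_seed(cfg$seed, {
    fr <- sim_frequencies_impl(cfg)
    nv <- cfg$n_variants
    ids <- unlist(lapply(seq_len(nrow(pops)), function(i)
      sprintf("%s_%02d", pops$label[i], seq_len(pops$n_samples[i]))))
    samples <- data.frame(
      sample_id = ids,
      group = rep(pops$group, pops$n_samples),
      population = rep(pops$label, pops$n_samples),
      stringsAsFactors = FALSE)
    n <- nrow(samples)

    dosage <- matrix(NA_integer_, n, nv)
    hap_idx <- c(fr$locus_index[!is.na(fr$locus_index)], fr$block_index)
    plain_idx <- setdiff(seq_len(nv), hap_idx)
    row0 <- 0L
    for (i in seq_len(nrow(pops))) {
      ns <- pops$n_samples[i]
      rows <- row0 + seq_len(ns)
      f <- fr$freq[, i]
      dosage[rows, plain_idx] <- rbinom(ns * length(plain_idx), 2L,
                                        rep(f[plain_idx], each = ns))
      if (length(hap_idx)) {
        p_sel <- f[fr$locus_index]
        h1 <- rbinom(ns, 1L, p_sel)
        h2 <- rbinom(ns, 1L, p_sel)
        dosage[rows, fr$locus_index] <- h1 + h2
        if (length(fr$block_index)) {
          nb <- length(fr$block_index)
          blk <- matrix(0L, ns, nb)
          for (h in list(h1, h2)) {
            base <- matrix(rbinom(ns * nb, 1L, rep(f[fr$block_index], each = ns)),
                           ns, nb)
            copy <- matrix(runif(ns * nb) < rep(fr$block_r, each = ns), ns, nb) &
                    (h == 1L)
            founder <- matrix(rep(fr$game_hap, each = ns), ns, nb)
            blk <- blk + ifelse(copy, founder, base)
          }
          dosage[rows, fr$block_index] <- blk
        }
      }
      row0 <- row0 + ns
    }

    # interleave invariant sites and order everything by position
    all_pos <- c(fr$positions, fr$invariant_positions)
    ni <- length(fr$invariant_positions)
    ord <- order(all_pos)
    dosage <- cbind(dosage, matrix(0L, n, ni))[, ord, drop = FALSE]
    is_invariant <- c(rep(FALSE, nv), rep(TRUE, ni))[ord]
    s <- nv + ni

    dp <- matrix(rpois(n * s, cfg$mean_depth), n, s)
    ad_alt <- matrix(0L, n, s)
    het <- which(dosage == 1L)
    ad_alt[het] <- rbinom(length(het), dp[het], 0.5)
    hom_ref <- which(dosage == 0L)
    ad_alt[hom_ref] <- rbinom(length(hom_ref), dp[hom_ref], cfg$hom_error_rate)
    hom_alt <- which(dosage == 2L)
    ad_alt[hom_alt] <- dp[hom_alt] -
      rbinom(length(hom_alt), dp[hom_alt], cfg$hom_error_rate)
    ad_alt[, is_invariant] <- 0L       # no alternate allele exists there
    ad_ref <- dp - ad_alt
    gq <- pmin(floor(cfg$gq_per_depth * dp), 99)
    storage.mode(gq) <- "integer"
    if (cfg$missing_rate > 0) {
      miss <- matrix(runif(n * s) < cfg$missing_rate, n, s)
      dosage[miss] <- NA_integer_; dp[miss] <- NA_integer_
      ad_ref[miss] <- NA_integer_; ad_alt[miss] <- NA_integer_
      gq[miss] <- NA_integer_
    }

    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, s, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
    alt[is_invariant] <- "."
    mq <- round(pmin(60, rnorm(s, 58, 2.5)), 2)
    mq0f <- round(pmax(0, rnorm(s, 0.02, 0.03)), 4)
    records <- data.frame(
      chrom = cfg$chrom_name, pos = all_pos[ord], ref = ref, alt = alt,
      mq = mq, mq0f = mq0f, is_indel = FALSE, is_multiallelic = FALSE,
      indel_distance = Inf, is_invariant = is_invariant,
      stringsAsFactors = FALSE)

    # record-row indices of the locus and block after interleaving
    locus_index <- if (is.na(fr$locus_index)) NA_integer_ else
      match(fr$positions[fr$locus_index], records$pos)
    block_index <- match(fr$positions[fr$block_index], records$pos)
    # the signal of interest is always generated clean so QC cannot remove it
    clean <- c(locus_index[!is.na(locus_index)], block_index)
    records$mq[clean] <- 60; records$mq0f[clean] <- 0

    site_ids <- paste0(records$chrom, ":", records$pos)
    dimn <- list(samples$sample_id, site_ids)
    dimnames(dosage) <- dimnames(dp) <- dimnames(ad_ref) <-
      dimnames(ad_alt) <- dimnames(gq) <- dimn
    calls <- genotype_calls(dosage, dp, ad_ref, ad_alt, gq)
    structure(list(samples = samples, records = records, calls = calls,
                   frequencies = fr, locus_index = locus_index,
                   block_index = block_index, config = cfg),
              class = "sim_cohort")
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("sim_cohort: %d samples, %d sites (%d invariant) on %s\n",
              nrow(x$samples), nrow(x$records), sum(x$records$is_invariant),
              x$config$chrom_name))
  invisible(x)
}
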