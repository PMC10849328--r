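#' Default population layout for simulated cohorts
#'
#' Two regional gene pools (a "home" region supplying most gamecocks and a
#' distant region supplying mostly nongame birds) each contribute one gamecock
#' and one nongame population. Totals are 48 gamecocks and 62 nongame birds,
#' the cohort sizes the association analysis is designed for. Within a region
#' the gamecock and nongame populations are genetically exchangeable
#' (`drift_F = 0`): the regional label carries all neutral structure, so the
#' phenotype is confounded with region but not with any finer structure.
#'
#' @return data.frame with columns `label`, `group`, `n_samples`, `drift_F`,
#'   `region`.
#' @export
default_populations <- function() {
  data.frame(
    label     = c("jpn_game", "jpn_nongame", "eth_game", "eth_nongame"),
    group     = c("gamecock", "nongame", "gamecock", "nongame"),
    n_samples = c(36L, 20L, 12L, 42L),
    drift_F   = c(0, 0, 0, 0),
    region    = c("JPN", "JPN", "ETH", "ETH"),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' All parameters of the synthetic-cohort generator. Defaults describe the
#' standard desk-scale cohort: one 10-Mb chromosome carrying 1,000 biallelic
#' SNPs and 1,000 invariant sites, four populations drifted from a common
#' ancestor under a hierarchical Balding-Nichols model (ancestral frequency
#' -> regional frequency -> population frequency), and one selected locus
#' whose "game" allele sits at frequency 0.895 in gamecocks and 0.037 in
#' nongame chickens, surrounded by a swept haplotype block.
#'
#' @param n_variants number of polymorphic SNPs.
#' @param n_invariant_sites number of monomorphic sites (written with ALT ".").
#' @param chrom_length_bp length of the single synthetic chromosome.
#' @param chrom_name chromosome name used in records and VCF output.
#' @param populations data.frame as [default_populations()]; columns `label`,
#'   `group` (gamecock/nongame/outgroup), `n_samples`, `drift_F` in `[0,1)`
#'   and optionally `region`.
#' @param regions data.frame with `label`, `drift_F`: shared regional drift
#'   applied before the per-population drift, or `NULL` for independent
#'   populations.
#' @param ancestral_freq_beta length-2 shape parameters of the Beta
#'   distribution the ancestral allele frequencies are drawn from.
#' @param selected_locus `NULL`, or a list with `pos` (bp),
#'   `freq_gamecock`, `freq_nongame`: population frequencies of the game
#'   allele forced at the locus for the two phenotype groups.
#' @param haplotype_block_bp width of the swept haplotype block centred on
#'   the selected locus; within the block a haplotype that carries the game
#'   allele copies a single founder haplotype with probability decaying
#'   linearly from 1 at the locus to 0 at the block edge. 0 disables it.
#' @param missing_rate per-call probability that a genotype is dropped.
#' @param mean_depth Poisson mean of per-call read depth.
#' @param gq_per_depth genotype quality model: `GQ = min(99, gq_per_depth*DP)`.
#' @param hom_error_rate per-read probability that a homozygous call shows a
#'   read of the other allele (gives the AD-ratio filter realistic near
#'   misses).
#' @param seed integer seed; all generator output is a pure function of the
#'   configuration including this seed.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_variants = 1000L,
                       n_invariant_sites = 1000L,
                       chrom_length_bp = 1e7,
                       chrom_name = "chrS",
                       populations = default_populations(),
                       regions = data.frame(label = c("JPN", "ETH"),
                                            drift_F = c(0.10, 0.10)),
                       ancestral_freq_beta = c(0.8, 0.8),
                       selected_locus = list(pos = 5e6,
                                             freq_gamecock = 0.895,
                                             freq_nongame = 0.037),
                       haplotype_block_bp = 1.6e6,
                       missing_rate = 0.03,
                       mean_depth = 15,
                       gq_per_depth = 3,
                       hom_error_rate = 0.005,
                       seed = 1L) {
  cfg <- structure(list(
    n_variants = as.integer(n_variants),
    n_invariant_sites = as.integer(n_invariant_sites),
    chrom_length_bp = as.numeric(chrom_length_bp),
    chrom_name = chrom_name,
    populations = populations,
    regions = regions,
    ancestral_freq_beta = as.numeric(ancestral_freq_beta),
    selected_locus = selected_locus,
    haplotype_block_bp = as.numeric(haplotype_block_bp),
    missing_rate = as.numeric(missing_rate),
    mean_depth = as.numeric(mean_depth),
    gq_per_depth = as.numeric(gq_per_depth),
    hom_error_rate = as.numeric(hom_error_rate),
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param cfg a `sim_config` object.
#' @export
validate_sim_config <- function(cfg) {
  p <- cfg$populations
  assert_that(is.data.frame(p) && nrow(p) >= 1,
              "populations must be a non-empty data.frame")
  assert_that(all(c("label", "group", "n_samples", "drift_F") %in% names(p)),
              "populations needs columns label, group, n_samples, drift_F")
  assert_that(!anyDuplicated(p$label), "population labels must be unique")
  assert_that(all(p$group %in% .valid_groups),
              "population group must be gamecock, nongame or outgroup")
  assert_that(all(p$n_samples >= 1), "population sample sizes must be >= 1")
  assert_that(all(p$drift_F >= 0 & p$drift_F < 1), "drift_F must be in [0,1)")
  if (!is.null(cfg$regions)) {
    assert_that(all(cfg$regions$drift_F >= 0 & cfg$regions$drift_F < 1),
                "region drift_F must be in [0,1)")
    if ("region" %in% names(p))
      assert_that(all(is.na(p$region) | p$region %in% cfg$regions$label),
                  "population region labels must appear in regions")
  }
  assert_that(cfg$n_variants >= 1, "need at least one variant")
  assert_that(cfg$n_invariant_sites >= 0, "n_invariant_sites must be >= 0")
  assert_that(cfg$chrom_length_bp >= cfg$n_variants + cfg$n_invariant_sites,
              "chromosome too short for the requested number of sites")
  assert_that(all(cfg$ancestral_freq_beta > 0),
              "ancestral_freq_beta shapes must be positive")
  sl <- cfg$selected_locus
  if (!is.null(sl)) {
    assert_that(sl$pos >= 1 && sl$pos <= cfg$chrom_length_bp,
                "selected locus position must lie on the chromosome")
    assert_that(sl$freq_gamecock >= 0 && sl$freq_gamecock <= 1 &&
                sl$freq_nongame >= 0 && sl$freq_nongame <= 1,
                "selected-locus frequencies must be in [0,1]")
  }
  assert_that(cfg$missing_rate >= 0 && cfg$missing_rate < 1,
              "missing_rate must be in [0,1)")
  assert_that(cfg$mean_depth > 0, "mean_depth must be positive")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d variants + %d invariant sites on %s (%.1f Mb), seed %d\n",
    x$n_variants, x$n_invariant_sites, x$chrom_name,
    x$chrom_length_bp / 1e6, x$seed))
  cat(sprintf("  populations: %s\n",
              paste(sprintf("%s(%s,n=%d)", x$populations$label,
                            x$populations$group, x$populations$n_samples),
                    collapse = ", ")))
  if (!is.null(x$selected_locus))
    cat(sprintf("  selected locus at %s bp: %.3f (gamecock) / %.3f (nongame)\n",
                format(x$selected_locus$pos, big.mark = ","),
                x$selected_locus$freq_gamecock, x$selected_locus$freq_nongame))
  invisible(x)
}
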