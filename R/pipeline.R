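#' Pipeline run configuration
#'
#' Bundles every stage's settings: input (a [sim_config()] or a VCF/sheet
#' pair), QC thresholds, window specifications, association and structure
#' settings, and the root seed all stochastic stages derive from.
#'
#' @param outdir output directory (created if absent).
#' @param sim a [sim_config()] to generate the cohort, or `NULL` to read
#'   `vcf`/`sheet`.
#' @param vcf,sheet,mask input paths (`mask` optional BED of retained
#'   regions); validated before any compute.
#' @param thresholds a [filter_thresholds()].
#' @param pbs_window,het_window [window_spec()]s for the PBS and
#'   heterozygosity scans (defaults: 1000/200 and 10000/1000 variants).
#' @param pbs_populations character vector `c(focal, contrast1, contrast2)`
#'   of population labels for the PBS scan, or `NULL` to skip it.
#' @param pi_region region (string or list) for nucleotide diversity, or
#'   `NULL` to use the simulated selected-locus block (skipped otherwise).
#' @param k_range candidate stratum counts for [select_k()].
#' @param n_perm permutations for [permutation_p()].
#' @param prune a [prune_spec()].
#' @param n_components principal components to report.
#' @param seed root seed recorded in the manifest.
#' @param write_vcf also write the simulated cohort as VCF + sheet?
#' @return validated list of class `run_config`.
#' @export
run_config <- function(outdir,
                       sim = sim_config(),
                       vcf = NULL, sheet = NULL, mask = NULL,
                       thresholds = filter_thresholds(),
                       pbs_window = window_spec(1000, 200),
                       het_window = window_spec(10000, 1000),
                       pbs_populations = c("jpn_game", "jpn_nongame",
                                           "eth_nongame"),
                       pi_region = NULL,
                       k_range = 1:6,
                       n_perm = 10000L,
                       prune = prune_spec(),
                       n_components = 10L,
                       seed = 1L,
                       write_vcf = FALSE) {
  assert_that(!is.null(sim) || (!is.null(vcf) && !is.null(sheet)),
              "provide either a sim_config or vcf + sheet paths")
  for (p in c(vcf, sheet, mask))
    assert_that(file.exists(p), sprintf("input path does not exist: %s", p))
  if (!is.null(sim)) validate_sim_config(sim)
  structure(list(outdir = outdir, sim = sim, vcf = vcf, sheet = sheet,
                 mask = mask, thresholds = thresholds,
                 pbs_window = pbs_window, het_window = het_window,
                 pbs_populations = pbs_populations, pi_region = pi_region,
                 k_range = k_range, n_perm = as.integer(n_perm),
                 prune = prune, n_components = as.integer(n_components),
                 seed = as.integer(seed), write_vcf = isTRUE(write_vcf)),
            class = "run_config")
}

write_tsv <- function(df, path, comments = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste("#", comments), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Executes simulate/read -> filter -> scan -> assoc -> structure, writing
#' one TSV per result plus a JSON manifest (versions, seed, input checksums,
#' per-stage record counts, output checksums). Re-running the same
#' configuration reproduces identical outputs byte for byte. A stage
#' failure halts the run with the stage name.
#'
#' @param cfg a [run_config()].
#' @param quiet suppress progress messages?
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  t0 <- Sys.time()
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e))))
  }
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$outdir, f)
  manifest <- list(package = "gamescan",
                   version = as.character(packageVersion("gamescan")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   seed = cfg$seed, counts = list(), inputs = list())

  # ---- stage 1: cohort ----
  co <- stage("input", {
    if (!is.null(cfg$sim)) {
      say("simulating cohort (seed %d)", cfg$sim$seed)
      simulate_cohort(cfg$sim)
    } else {
      say("reading %s", cfg$vcf)
      manifest$inputs <- as.list(tools::md5sum(c(cfg$vcf, cfg$sheet)))
      read_vcf(cfg$vcf, cfg$sheet)
    }
  })
  if (cfg$write_vcf && !is.null(cfg$sim)) {
    write_vcf(co$samples, co$records, co$calls, out("sim.vcf.gz"))
    write_sample_sheet(co$samples, out("samples.tsv"))
  }
  manifest$counts$samples <- nrow(co$samples)
  manifest$counts$sites <- nrow(co$records)

  # ---- stage 2: filters ----
  filt <- stage("filter", {
    md <- mean_autosomal_depth(co$calls, co$records)
    gf <- apply_genotype_filters(co$calls, cfg$thresholds, md)
    sf <- apply_site_filters(co$records, gf$calls, cfg$mask, cfg$thresholds)
    calls <- subset_calls(gf$calls, variants = sf$keep)
    records <- co$records[sf$keep, , drop = FALSE]
    qc <- sample_qc(calls, cfg$thresholds)
    keep_s <- qc$verdict == "KEPT"
    list(calls = subset_calls(calls, samples = keep_s),
         samples = co$samples[keep_s, , drop = FALSE],
         records = records, qc = qc,
         report = rbind(
           data.frame(level = "genotype", reason = names(gf$report$counts),
                      n = unname(gf$report$counts)),
           data.frame(level = "site", reason = names(sf$report$counts),
                      n = unname(sf$report$counts))))
  })
  say("filters: %d/%d sites kept, %d/%d samples kept",
      nrow(filt$records), nrow(co$records), nrow(filt$samples),
      nrow(co$samples))
  write_tsv(filt$report, out("filter_report.tsv"),
            "per-reason masked-call / dropped-site counts")
  write_tsv(filt$qc, out("sample_qc.tsv"),
            "missing_frac over kept sites; contamination advisory")
  manifest$counts$sites_kept <- nrow(filt$records)
  manifest$counts$samples_kept <- nrow(filt$samples)

  calls <- filt$calls; records <- filt$records; samples <- filt$samples
  mac_keep <- which(frequency_filters(calls, "mac", thresholds = cfg$thresholds) &
                    !records$is_invariant)
  maf_keep <- which(frequency_filters(calls, "maf", thresholds = cfg$thresholds) &
                    !records$is_invariant)
  manifest$counts$variants_mac <- length(mac_keep)
  manifest$counts$variants_maf <- length(maf_keep)

  # ---- stage 3: selection scans ----
  stage("scan", {
    recs <- records[mac_keep, , drop = FALSE]
    if (!is.null(cfg$pbs_populations)) {
      labs <- cfg$pbs_populations
      cnt <- lapply(labs, function(l)
        allele_counts(subset_calls(calls, variants = mac_keep),
                      samples$population == l))
      pbs <- pbs_windows(cnt[[1]], cnt[[2]], cnt[[3]], cfg$pbs_window, recs)
      write_tsv(pbs, out("pbs.tsv"),
                sprintf("PBS, focal=%s contrasts=%s,%s; windows of %d variants, step %d",
                        labs[1], labs[2], labs[3],
                        cfg$pbs_window$size_variants,
                        cfg$pbs_window$step_variants))
      manifest$counts$pbs_windows <- nrow(pbs)
    }
    for (g in intersect(c("gamecock", "nongame"), samples$group)) {
      het <- windowed_heterozygosity(subset_calls(calls, variants = mac_keep),
                                     samples$group == g, cfg$het_window, recs)
      write_tsv(het, out(sprintf("het_%s.tsv", g)),
                sprintf("observed heterozygosity, %s; windows of %d variants, step %d",
                        g, cfg$het_window$size_variants,
                        cfg$het_window$step_variants))
      manifest$counts[[paste0("het_windows_", g)]] <- nrow(het)
    }
    region <- cfg$pi_region
    if (is.character(region)) region <- parse_region(region)
    if (is.null(region) && !is.null(cfg$sim) &&
        !is.null(cfg$sim$selected_locus)) {
      half <- max(cfg$sim$haplotype_block_bp / 2, 1)
      region <- list(chrom = cfg$sim$chrom_name,
                     start = cfg$sim$selected_locus$pos - half,
                     end = cfg$sim$selected_locus$pos + half)
    }
    if (!is.null(region)) {
      pis <- lapply(intersect(c("gamecock", "nongame"), samples$group),
        function(g) {
          pi <- pi_invariant_aware(calls, records, samples$group == g, region)
          data.frame(group = g, pi = pi$pi, n_sites = pi$n_sites,
                     diffs = pi$diffs, comps = pi$comps)
        })
      write_tsv(do.call(rbind, pis), out("pi.tsv"),
                sprintf("pixy-style nucleotide diversity in %s:%d-%d (invariant sites included)",
                        region$chrom, round(region$start), round(region$end)))
    }
  })

  # LD-pruned variant set: the basis for IBS clustering and PCA, so that one
  # locally swept haplotype block cannot dominate genome-wide relatedness
  pruned <- stage("prune", ld_prune(calls, records, cfg$prune, mac_keep))

  # ---- stage 4: association ----
  assoc <- stage("assoc", {
    case <- samples$group == "gamecock"
    assert_that(any(case) && any(!case),
                "association needs both gamecocks and nongame samples")
    say("IBS clustering and K selection (K in %s)",
        paste(range(cfg$k_range), collapse = ":"))
    dist <- ibs_distance(calls, variants = pruned)
    sel <- select_k(calls, case, cfg$k_range, dist, maf_keep)
    write_tsv(sel$table, out("lambda_by_k.tsv"),
              "genomic inflation by stratum count; chosen K minimises lambda")
    write_tsv(data.frame(sample_id = samples$sample_id,
                         cluster = sel$partition$assignment),
              out("clusters.tsv"), sprintf("K = %d", sel$best_k))
    res <- assoc_cmh(calls, case, sel$partition, maf_keep)
    gc <- genomic_control(res$chi2)
    say("K = %d, lambda = %.3f; %d permutations", sel$best_k, gc$lambda,
        cfg$n_perm)
    perm <- permutation_p(calls, case, sel$partition, cfg$n_perm,
                          seed = cfg$seed, variants = maf_keep)
    freqs <- group_allele_frequencies(subset_calls(calls, variants = maf_keep),
                                      samples)
    tab <- data.frame(
      chrom = records$chrom[maf_keep], pos = records$pos[maf_keep],
      ref = records$ref[maf_keep], alt = records$alt[maf_keep],
      freq_case = freqs[, "gamecock"], freq_control = freqs[, "nongame"],
      chi2 = res$chi2, p_raw = res$p, lambda = gc$lambda,
      p_gc = gc$p_adj, p_perm = perm$p_perm,
      significant = perm$significant)
    write_tsv(tab, out("assoc.tsv"),
              c("stratified CMH on allele counts; genomic control;",
                sprintf("within-cluster permutation p (n = %d), significant iff p_perm < 1e-4",
                        cfg$n_perm)))
    manifest$counts$assoc_variants <- nrow(tab)
    manifest$counts$assoc_significant <- sum(tab$significant, na.rm = TRUE)
    list(best_k = sel$best_k, lambda = gc$lambda, table = tab)
  })

  # ---- stage 5: structure ----
  stage("structure", {
    kept <- pruned
    write_tsv(data.frame(chrom = records$chrom[kept], pos = records$pos[kept]),
              out("pruned_variants.tsv"),
              sprintf("LD-pruned variant set (window %d bp, step %d bp, r2 > %.2f)",
                      cfg$prune$window_bp, cfg$prune$step_bp,
                      cfg$prune$r2_threshold))
    ncomp <- min(cfg$n_components, length(kept), nrow(samples) - 1)
    pca <- pca_genotypes(calls, kept, ncomp)
    write_tsv(cbind(data.frame(sample_id = samples$sample_id,
                               group = samples$group,
                               population = samples$population),
                    as.data.frame(pca$scores)),
              out("pca.tsv"), "genotype PCA on the LD-pruned variant set")
    manifest$counts$pruned_variants <- length(kept)
  })

  outputs <- setdiff(list.files(cfg$outdir, full.names = TRUE),
                     out("manifest.json"))
  manifest$outputs <- as.list(tools::md5sum(sort(outputs)))
  names(manifest$outputs) <- basename(names(manifest$outputs))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  say("done in %.1f s; manifest at %s", as.numeric(Sys.time() - t0, units = "secs"),
      out("manifest.json"))
  invisible(manifest)
}
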