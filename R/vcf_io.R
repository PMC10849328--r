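#' Write cohort genotypes as VCF v4.2
#'
#' Emits one record per site with `FORMAT GT:DP:AD:GQ` and `INFO MQ`/`MQ0F`.
#' Invariant sites are written with `ALT = "."` (and a single AD value, the
#' reference depth). Missing calls become `./.:.:.:.`. A path ending in
#' `.gz` is gzip-compressed.
#'
#' @param samples data.frame with at least `sample_id`; column order defines
#'   the VCF sample columns.
#' @param records site annotation data.frame as produced by
#'   [simulate_cohort()] (columns `chrom`, `pos`, `ref`, `alt`, `mq`,
#'   `mq0f`); must be position-sorted within chromosome.
#' @param calls a [genotype_calls()] aligned with `samples` and `records`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(samples, records, calls, path) {
  assert_that(nrow(records) == n_variants(calls),
              "records and calls disagree on the number of sites")
  assert_that(nrow(samples) == n_samples(calls),
              "samples and calls disagree on the number of samples")
  check_sorted_records(records)
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", unique(records$chrom)),
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=MQ0F,Number=1,Type=Float,Description=\"Fraction of MQ0 reads\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples$sample_id), collapse = "\t"))

  gt <- matrix(c("0/0", "0/1", "1/1")[calls$dosage + 1L],
               nrow(calls$dosage), ncol(calls$dosage))
  gt[is.na(calls$dosage)] <- "./."
  num <- function(m) { x <- format(m, trim = TRUE); x[is.na(m)] <- "."; x }
  dp <- num(calls$dp); gq <- num(calls$gq)
  ad <- matrix(paste(num(calls$ad_ref), num(calls$ad_alt), sep = ","),
               nrow(gt), ncol(gt))
  inv <- records$alt == "."
  if (any(inv)) ad[, inv] <- num(calls$ad_ref[, inv, drop = FALSE])
  ad[is.na(calls$ad_ref)] <- "."
  geno <- matrix(paste(gt, dp, ad, gq, sep = ":"), nrow(gt), ncol(gt))

  info <- sprintf("MQ=%s;MQ0F=%s", format(records$mq, trim = TRUE),
                  format(records$mq0f, trim = TRUE, scientific = FALSE))
  body <- paste(records$chrom, records$pos, ".", records$ref, records$alt,
                ".", ".", info, "GT:DP:AD:GQ",
                apply(geno, 2, paste, collapse = "\t"), sep = "\t")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Read a VCF into the pipeline's containers
#'
#' Parses `GT`, `DP`, `AD`, `GQ` and the `MQ`/`MQ0F` INFO annotations.
#' Invariant sites (`ALT = "."`) are retained with all-reference dosage where
#' called; `./.` genotypes become missing. Site annotations gain
#' `is_indel`, `is_multiallelic` and `indel_distance` (bp from a SNP to the
#' nearest base of the nearest indel's reference span, `Inf` when the file
#' holds no indels).
#'
#' @param path VCF file (optionally bgzipped/gzipped).
#' @param sample_sheet optional data.frame (`sample_id`, `group`,
#'   `population`) or path to such a TSV; every sheet sample must be present
#'   in the VCF, and the returned calls are restricted to (and ordered as)
#'   the sheet.
#' @return list with `samples`, `records` and `calls`, aligned as in
#'   [simulate_cohort()].
#' @export
read_vcf <- function(path, sample_sheet = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  chrom <- fix[, "CHROM"]
  pos <- as.numeric(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]; alt[is.na(alt)] <- "."
  records <- data.frame(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    mq = suppressWarnings(vcfR::extract.info(v, "MQ", as.numeric = TRUE)),
    mq0f = suppressWarnings(vcfR::extract.info(v, "MQ0F", as.numeric = TRUE)),
    stringsAsFactors = FALSE)
  records$is_invariant <- records$alt == "."
  records$is_multiallelic <- grepl(",", records$alt, fixed = TRUE)
  first_alt <- sub(",.*$", "", records$alt)
  records$is_indel <- !records$is_invariant &
    (nchar(records$ref) != 1L | (nchar(first_alt) != 1L & first_alt != "."))
  records$indel_distance <- indel_distances(records)
  check_sorted_records(records)

  gt <- t(vcfR::extract.gt(v, "GT"))
  dosage <- gt_to_dosage(gt)
  dp <- t(vcfR::extract.gt(v, "DP", as.numeric = TRUE))
  gq <- t(vcfR::extract.gt(v, "GQ", as.numeric = TRUE))
  ad <- t(vcfR::extract.gt(v, "AD"))
  ad_ref <- matrix(NA_integer_, nrow(ad), ncol(ad))
  ad_alt <- ad_ref
  ok <- !is.na(ad) & ad != "."
  if (any(ok)) {
    parts <- strsplit(ad[ok], ",", fixed = TRUE)
    ad_ref[ok] <- as.integer(vapply(parts, `[`, "", 1L))
    ad_alt[ok] <- as.integer(vapply(parts, function(p)
      if (length(p) >= 2L) p[2L] else "0", ""))
  }
  site_ids <- paste0(records$chrom, ":", records$pos)
  dimn <- list(rownames(gt), site_ids)
  storage.mode(dp) <- "integer"; storage.mode(gq) <- "integer"
  dimnames(dosage) <- dimnames(dp) <- dimnames(gq) <-
    dimnames(ad_ref) <- dimnames(ad_alt) <- dimn
  calls <- genotype_calls(dosage, dp, ad_ref, ad_alt, gq)

  samples <- data.frame(sample_id = rownames(gt), group = NA_character_,
                        population = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(sample_sheet)) {
    sheet <- if (is.character(sample_sheet)) read_sample_sheet(sample_sheet)
             else sample_sheet
    missing <- setdiff(sheet$sample_id, samples$sample_id)
    assert_that(length(missing) == 0L,
                paste("sample sheet entries absent from VCF:",
                      paste(missing, collapse = ", ")))
    calls <- subset_calls(calls, samples = sheet$sample_id)
    samples <- sheet
  }
  list(samples = samples, records = records, calls = calls)
}

# "0/0"-style diploid GT strings -> dosage; anything unrecognised errors.
gt_to_dosage <- function(gt) {
  map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
           "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L,
           "./." = NA_integer_, ".|." = NA_integer_, "." = NA_integer_)
  d <- map[gt]
  bad <- !is.na(gt) & !(gt %in% names(map))
  assert_that(!any(bad), paste("malformed GT field(s):",
              paste(unique(gt[bad])[1:min(3, sum(bad))], collapse = ", ")))
  matrix(d, nrow(gt), ncol(gt))
}

check_sorted_records <- function(records) {
  for (ch in unique(records$chrom)) {
    p <- records$pos[records$chrom == ch]
    assert_that(all(diff(p) > 0),
                sprintf("records not strictly position-sorted on %s", ch))
  }
  invisible(records)
}

#' Distance from each site to the nearest indel's reference span
#'
#' @param records site annotation data.frame with `chrom`, `pos`, `ref` and
#'   `is_indel`.
#' @return numeric vector, 0 for indels themselves, `Inf` when the
#'   chromosome carries no indel.
#' @export
indel_distances <- function(records) {
  out <- rep(Inf, nrow(records))
  for (ch in unique(records$chrom)) {
    i <- which(records$chrom == ch)
    ind <- i[records$is_indel[i]]
    if (!length(ind)) next
    starts <- records$pos[ind]
    ends <- records$pos[ind] + nchar(records$ref[ind]) - 1L
    for (j in i) {
      d <- pmax(0, pmax(starts - records$pos[j], records$pos[j] - ends))
      out[j] <- min(d)
    }
  }
  out
}

#' Read / write the sample sheet
#'
#' Tab-separated with header `sample_id`, `group`, `population`; `group`
#' must be `gamecock`, `nongame` or `outgroup`.
#'
#' @param path TSV file.
#' @return data.frame with the three columns.
#' @export
read_sample_sheet <- function(path) {
  sheet <- read.delim(path, stringsAsFactors = FALSE)
  assert_that(all(c("sample_id", "group", "population") %in% names(sheet)),
              "sample sheet needs columns sample_id, group, population")
  assert_that(!anyDuplicated(sheet$sample_id), "sample ids must be unique")
  assert_that(all(sheet$group %in% .valid_groups),
              "group must be gamecock, nongame or outgroup")
  sheet[, c("sample_id", "group", "population")]
}

#' @rdname read_sample_sheet
#' @param samples data.frame to write.
#' @export
write_sample_sheet <- function(samples, path) {
  write.table(samples[, c("sample_id", "group", "population")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
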