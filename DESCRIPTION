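Package: gamescan
Title: Selection Scans and Stratified Association for Gamecock Population Genomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale population-genetics pipeline for locating loci that
    distinguish gamecocks from nongame chickens. Implements hard genotype, site
    and sample filtering of diploid biallelic VCF data; windowed selection
    statistics (Hudson's FST, the population branch statistic, observed
    heterozygosity, and invariant-site-aware nucleotide diversity); identity-by-
    state cluster-stratified Cochran-Mantel-Haenszel association with genomic
    control and within-cluster permutation significance; LD pruning and genotype
    PCA; and a Balding-Nichols cohort simulator so every stage can be exercised
    and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
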