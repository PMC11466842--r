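Package: msmix
Title: Multi-SNP Marker Screening, Error-Corrected Allele Calling and
    DNA Mixture Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for forensic DNA mixture analysis with short multi-SNP
    (microhaplotype-style) amplicon panels. Screens phased population
    genotypes for polymorphic multi-SNP markers with the D-value diversity
    statistic, extracts per-locus haplotype alleles from aligned paired-end
    amplicon reads with paired-read concordance filtering, estimates
    locus-specific mismatch-count-dependent error profiles from single-source
    samples, separates true minor alleles from PCR and sequencing artifacts
    with an iterative binomial test under false discovery rate control,
    applies read-ratio genotyping rules, computes forensic population
    statistics (heterozygosity, match probability, discrimination power,
    power of exclusion, Hardy-Weinberg tests), scores mixture experiments,
    and simulates panels, populations, single-source samples and mixtures
    with a two-layer (PCR + sequencing) error model and full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    rlang,
    methods,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    GenomicAlignments,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
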