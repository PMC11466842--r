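# Independent oracles and fixture builders shared across the suite.

# Exhaustive pairwise D-value oracle: per unordered pair of individuals,
# compare the unordered diploid genotype at every SNP position and count the
# pair when >= min_diff positions differ. Deliberately written from scratch
# (strsplit + sorted base pairs), independent of compute_d_value().
oracle_d_value <- function(hap1, hap2, min_diff = 2) {
  n <- length(hap1)
  geno <- lapply(seq_len(n), function(i) {
    a <- strsplit(hap1[i], "")[[1]]
    b <- strsplit(hap2[i], "")[[1]]
    mapply(function(x, y) paste(sort(c(x, y)), collapse = ""), a, b)
  })
  t_count <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (sum(geno[[i]] != geno[[j]]) >= min_diff) t_count <- t_count + 1L
    }
  }
  list(t = t_count, n_pairs = choose(n, 2), d = t_count / choose(n, 2))
}

# Exact binomial upper tail by explicit pmf summation.
oracle_binom_tail <- function(c, n, e) {
  if (c == 0) return(1)
  sum(vapply(c:n, function(k) {
    exp(lchoose(n, k) + k * log(e) + (n - k) * log1p(-e))
  }, numeric(1)))
}

# Random haplotype cohort over s SNPs for property tests.
random_cohort <- function(n, s, bases = c("A", "C")) {
  draw <- function() paste(sample(bases, s, replace = TRUE), collapse = "")
  tibble::tibble(
    hap1 = replicate(n, draw()),
    hap2 = replicate(n, draw())
  )
}

# Quick profile tibble builder: prof("L1", AAA = 100, AAT = 3)
prof <- function(locus_id, ...) {
  x <- c(...)
  tibble::tibble(locus_id = locus_id, allele = names(x),
                 count = as.integer(x))
}

# Minimal error profile object for caller tests: e_by_n named by n.
toy_error_profile <- function(locus_id, e_by_n, floor_rate = 1e-6) {
  ep <- tibble::tibble(
    locus_id = locus_id,
    n = as.integer(names(e_by_n)),
    e_rate = unname(e_by_n),
    n_samples = 1L, usable = TRUE
  )
  class(ep) <- c("msmix_error_profile", class(tibble::tibble()))
  attr(ep, "floor_rate") <- floor_rate
  ep
}

# Write a small phased VCF for screening tests.
write_toy_vcf <- function(path, chrom, pos, ref, alt, gt) {
  n_ind <- ncol(gt)
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", chrom[1], ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sprintf("S%02d", seq_len(n_ind))), collapse = "\t")
  )
  body <- vapply(seq_along(pos), function(i) {
    paste(c(chrom[i], pos[i], ".", ref[i], alt[i], ".", "PASS", ".", "GT",
            gt[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

# Write a SAM file from a record tibble (qname, flag, pos, cigar, seq).
write_toy_sam <- function(path, chrom, chrom_len, records) {
  lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    paste0("@SQ\tSN:", chrom, "\tLN:", chrom_len),
    vapply(seq_len(nrow(records)), function(i) {
      r <- records[i, ]
      paste(r$qname, r$flag, chrom, r$pos, 60, r$cigar, "=", r$pos, 0,
            r$seq, paste(rep("I", nchar(r$seq)), collapse = ""),
            sep = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  path
}
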