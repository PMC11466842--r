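# Forensic population statistics: He/Ho, MP/DP, PE, HWE, panel combination.

#' Allele coverage ratio (intra-locus balance)
#'
#' Balance of a heterozygous genotype's two allele depths: the smaller depth
#' divided by the larger. 1 means perfectly balanced coverage.
#'
#' @param depth_a,depth_b Read depths of the two alleles (vectorised).
#' @return `min / max` per pair; `NA` (with a warning) where a depth is 0.
#' @examples
#' acr(80, 100)
#' @export
acr <- function(depth_a, depth_b) {
  out <- pmin(depth_a, depth_b) / pmax(depth_a, depth_b)
  bad <- depth_a <= 0 | depth_b <= 0
  if (any(bad)) {
    warn("acr(): zero depth; ACR undefined for flagged genotypes")
    out[bad] <- NA_real_
  }
  out
}

# Levene exact HWE distribution for a biallelic locus: full enumeration over
# heterozygote counts compatible with the allele counts.
hwe_exact_biallelic <- function(n_het, n_a, n_total_alleles) {
  n <- n_total_alleles / 2
  n_b <- n_total_alleles - n_a
  hets <- seq.int(n_a %% 2L, min(n_a, n_b), by = 2L)
  logp <- lgamma(n + 1) -
    lgamma((n_a - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((n_b - hets) / 2 + 1) +
    hets * log(2) +
    lgamma(n_a + 1) + lgamma(n_b + 1) - lgamma(n_total_alleles + 1)
  p_obs <- logp[match(n_het, hets)]
  sum(exp(logp[logp <= p_obs + 1e-9]))
}

# Conditional-probability statistic of a genotype table (up to terms constant
# under allele permutation): h*log(2) - sum(log n_jk!).
hwe_table_stat <- function(a1, a2) {
  het <- sum(a1 != a2)
  g <- ifelse(a1 <= a2, paste(a1, a2), paste(a2, a1))
  het * log(2) - sum(lgamma(table(g) + 1))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Biallelic loci use complete enumeration of the Levene exact distribution
#' of heterozygote counts given the allele counts. Loci with three or more
#' alleles use a Monte-Carlo exact test: the `2n` alleles are permuted and
#' re-paired `reps` times and the conditional probability of each permuted
#' genotype table is compared to the observed one (the approach of the
#' standard forensic-genetics software for multi-allelic markers).
#'
#' @param allele1,allele2 The two alleles of each individual's genotype.
#' @param reps Monte-Carlo permutations for 3+ alleles (default 1e5).
#' @return The p-value. Monomorphic loci return 1.
#' @export
hwe_exact_test <- function(allele1, allele2, reps = 1e5) {
  stopifnot(length(allele1) == length(allele2))
  pool <- c(allele1, allele2)
  k <- length(unique(pool))
  if (k <= 1L) return(1)
  if (k == 2L) {
    counts <- table(pool)
    return(hwe_exact_biallelic(sum(allele1 != allele2), counts[[1]],
                               length(pool)))
  }
  obs <- hwe_table_stat(allele1, allele2)
  n <- length(allele1)
  hits <- 0L
  for (r in seq_len(reps)) {
    perm <- sample(pool)
    if (hwe_table_stat(perm[1:n], perm[(n + 1):(2 * n)]) <= obs + 1e-9) {
      hits <- hits + 1L
    }
  }
  (hits + 1) / (reps + 1)
}

#' Per-locus forensic statistics
#'
#' Computes, for each locus, allele frequencies by the counting method over
#' the `2n` chromosomes of successfully genotyped individuals, observed
#' heterozygosity `Ho` (heterozygote fraction), expected heterozygosity
#' `He = 1 - sum(p^2)`, match probability `MP` (sum of squared observed
#' genotype frequencies), discrimination power `DP = 1 - MP`, power of
#' exclusion `PE = h^2 (1 - 2 h H^2)` with `h = Ho`, `H = 1 - Ho`, and an
#' exact Hardy-Weinberg p-value ([hwe_exact_test()]).
#'
#' @param genotypes Genotype tibble across individuals with columns
#'   `locus_id`, `status`, `allele1`, `allele2` (e.g. stacked
#'   [genotype_sample()] outputs); only `homozygous`/`heterozygous` rows are
#'   used.
#' @param hwe_reps Monte-Carlo permutations for multi-allelic HWE tests.
#' @return An `msmix_locus_stats` tibble: `locus_id`, `n_individuals`,
#'   `n_alleles`, `Ho`, `He`, `MP`, `DP`, `PE`, `hwe_p`, and the frequency
#'   table as a list column `allele_freqs`.
#' @export
locus_stats <- function(genotypes, hwe_reps = 1e5) {
  g <- genotypes %>%
    filter(.data$status %in% c("homozygous", "heterozygous")) %>%
    select("locus_id", "allele1", "allele2")
  if (nrow(g) == 0L) {
    abort("locus_stats(): no successfully genotyped individuals")
  }
  one_locus <- function(d, key) {
    n <- nrow(d)
    if (n < 2L) {
      abort(paste0("locus_stats(): fewer than 2 genotyped individuals at ",
                   key$locus_id))
    }
    pool <- c(d$allele1, d$allele2)
    freqs <- table(pool) / (2 * n)
    ho <- mean(d$allele1 != d$allele2)
    he <- 1 - sum(freqs^2)
    gcode <- ifelse(d$allele1 <= d$allele2,
                    paste(d$allele1, d$allele2),
                    paste(d$allele2, d$allele1))
    mp <- sum((table(gcode) / n)^2)
    h <- ho
    capH <- 1 - h
    pe <- h^2 * (1 - 2 * h * capH^2)
    tibble(
      n_individuals = n, n_alleles = length(freqs),
      Ho = ho, He = he, MP = mp, DP = 1 - mp, PE = pe,
      hwe_p = hwe_exact_test(d$allele1, d$allele2, reps = hwe_reps),
      allele_freqs = list(tibble(allele = names(freqs),
                                 freq = as.numeric(freqs)))
    )
  }
  out <- g %>%
    group_by(.data$locus_id) %>%
    dplyr::group_modify(one_locus) %>%
    ungroup()
  msmix_tbl(out, "msmix_locus_stats")
}

#' Combine per-locus statistics into panel-level statistics
#'
#' Combined match probability `CMP = prod(MP_l)`, total discrimination power
#' `TDP = 1 - CMP`, combined power of exclusion
#' `CPE = 1 - prod(1 - PE_l)`, and the Bonferroni-corrected per-locus HWE
#' significance threshold `family_alpha / L`. Products are accumulated in
#' log space; `CMP` is also reported as `log10_cmp` because the plain
#' product underflows for panels of hundreds of loci.
#'
#' @param stats An `msmix_locus_stats` tibble (or any tibble with `MP`,
#'   `PE`); rows with `NA` statistics are dropped.
#' @param family_alpha Family-wise HWE significance level (default 0.05).
#' @return A one-row tibble: `n_loci`, `cmp`, `log10_cmp`, `tdp`, `cpe`,
#'   `bonferroni_alpha`.
#' @examples
#' combine_panel(tibble::tibble(MP = c(0.5, 0.5), PE = c(0.1, 0.2)))
#' @export
combine_panel <- function(stats, family_alpha = 0.05) {
  s <- stats[!is.na(stats$MP) & !is.na(stats$PE), , drop = FALSE]
  if (nrow(s) == 0L) abort("combine_panel(): at least 1 locus required")
  log_cmp <- sum(log(s$MP))
  tibble(
    n_loci = nrow(s),
    cmp = exp(log_cmp),
    log10_cmp = log_cmp / log(10),
    tdp = -expm1(log_cmp),
    cpe = -expm1(sum(log1p(-s$PE))),
    bonferroni_alpha = family_alpha / nrow(s)
  )
}
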