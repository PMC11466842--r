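# Single-source genotyping by depth and allele-ratio (alpha) rules.

#' Genotype one locus of a single-source sample
#'
#' Applies the depth and alpha-ratio rules. The major allele is the
#' best-supported allele (ties towards the lexicographically smallest
#' string). Loci whose major allele depth is not strictly greater than
#' `min_depth` are `low_depth`. Otherwise each non-major allele gets an
#' alpha value, its count divided by the major's count:
#'
#' * all alpha `< hom_alpha` (0.05): `homozygous` for the major allele;
#' * exactly one allele with alpha in `[hom_alpha, het_alpha_max]` (0.05-0.2,
#'   both ends inclusive) and every other alpha `< hom_alpha`:
#'   `heterozygous` major/that allele;
#' * any other configuration: `failed`.
#'
#' @param profile Profile tibble for one locus (`locus_id`, `allele`,
#'   `count`); zero rows give `low_depth`.
#' @param min_depth Major-allele depth gate; genotyping requires depth
#'   strictly greater than this (default 50).
#' @param hom_alpha Upper bound (exclusive) for artifact-level alpha
#'   (default 0.05).
#' @param het_alpha_max Upper bound (inclusive) of the heterozygous alpha
#'   interval (default 0.2).
#' @return A one-row tibble: `locus_id`, `status` (`homozygous`,
#'   `heterozygous`, `failed`, `low_depth`), `allele1`, `allele2`,
#'   `major_depth`, `minor_depth`, `alpha` (the het partner's ratio, else the
#'   largest non-major alpha, `NA` if none).
#' @examples
#' genotype_locus(tibble::tibble(locus_id = "L1",
#'                               allele = c("AAA", "AAT"),
#'                               count = c(100L, 10L)))
#' @export
genotype_locus <- function(profile, min_depth = 50, hom_alpha = 0.05,
                           het_alpha_max = 0.2) {
  if (nrow(profile) == 0L) {
    return(tibble(locus_id = NA_character_, status = "low_depth",
                  allele1 = NA_character_, allele2 = NA_character_,
                  major_depth = 0L, minor_depth = 0L, alpha = NA_real_))
  }
  lid <- unique(profile$locus_id)
  if (length(lid) != 1L) {
    abort("genotype_locus(): profile must cover exactly one locus")
  }
  ord <- order(-profile$count, profile$allele)
  al <- profile$allele[ord]
  ct <- profile$count[ord]
  major <- al[1]
  major_depth <- ct[1]
  if (major_depth <= min_depth) {
    return(tibble(locus_id = lid, status = "low_depth", allele1 = major,
                  allele2 = NA_character_,
                  major_depth = as.integer(major_depth), minor_depth = 0L,
                  alpha = NA_real_))
  }
  if (length(al) == 1L) {
    return(tibble(locus_id = lid, status = "homozygous", allele1 = major,
                  allele2 = major, major_depth = as.integer(major_depth),
                  minor_depth = 0L, alpha = NA_real_))
  }
  alpha <- ct[-1] / major_depth
  in_het <- alpha >= hom_alpha & alpha <= het_alpha_max
  below <- alpha < hom_alpha
  if (all(below)) {
    tibble(locus_id = lid, status = "homozygous", allele1 = major,
           allele2 = major, major_depth = as.integer(major_depth),
           minor_depth = 0L, alpha = max(alpha))
  } else if (sum(in_het) == 1L && all(below | in_het)) {
    het <- which(in_het)
    tibble(locus_id = lid, status = "heterozygous", allele1 = major,
           allele2 = al[-1][het], major_depth = as.integer(major_depth),
           minor_depth = as.integer(ct[-1][het]), alpha = alpha[het])
  } else {
    tibble(locus_id = lid, status = "failed", allele1 = major,
           allele2 = NA_character_, major_depth = as.integer(major_depth),
           minor_depth = 0L, alpha = max(alpha))
  }
}

#' Genotype every locus of a single-source sample
#'
#' Runs [genotype_locus()] per locus of a profile. By default genotyping
#' consumes the raw concordant-read profile; `use_calls` instead restricts
#' each locus to the alleles a call set accepted as true (major + minor)
#' before applying the same rules.
#'
#' @param profiles Profile tibble over loci (`locus_id`, `allele`, `count`).
#' @param use_calls Optional `msmix_calls` tibble; when supplied, artifact
#'   alleles are removed before genotyping.
#' @inheritParams genotype_locus
#' @return An `msmix_genotypes` tibble, one row per locus.
#' @export
genotype_sample <- function(profiles, min_depth = 50, hom_alpha = 0.05,
                            het_alpha_max = 0.2, use_calls = NULL) {
  if (!is.null(use_calls)) {
    profiles <- profiles %>%
      semi_join(true_alleles(use_calls), by = c("locus_id", "allele"))
  }
  if (nrow(profiles) == 0L) {
    return(msmix_tbl(tibble(locus_id = character(), status = character(),
                            allele1 = character(), allele2 = character(),
                            major_depth = integer(), minor_depth = integer(),
                            alpha = numeric()), "msmix_genotypes"))
  }
  out <- profiles %>%
    group_by(.data$locus_id) %>%
    dplyr::group_map(~ genotype_locus(mutate(.x, locus_id = .y$locus_id),
                                      min_depth = min_depth,
                                      hom_alpha = hom_alpha,
                                      het_alpha_max = het_alpha_max)) %>%
    bind_rows()
  msmix_tbl(out, "msmix_genotypes")
}
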