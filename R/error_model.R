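# Locus-specific, mismatch-count-specific error profile e_l(n).

#' Estimate per-locus error profiles from single-source samples
#'
#' At a multi-SNP locus of a single-source sample, at most two alleles can be
#' real; everything else is a technical artifact. Per sample and locus the
#' two best-supported alleles are designated true (subject to the
#' homozygote rule below), every other allele is an error whose mismatch
#' count `n` is its minimum Hamming distance to a true allele, and
#' `ratio(n)` is the fraction of the locus's retained reads carried by
#' distance-`n` artifacts. The profile entry `e_l(n)` is the mean of
#' `ratio(n)` over samples with coverage at the locus.
#'
#' Homozygote rule: when the second-ranked allele holds less than
#' `hom_alpha` of the top allele's reads it is itself treated as an artifact
#' (a homozygous sample), so that genuine artifacts are not mistaken for a
#' second true allele and deflate the profile. Ties for second place are
#' conservative: all tied alleles count as errors.
#'
#' Mismatch counts never observed at a locus receive `floor_rate`, and the
#' profile is made non-increasing in `n` by a pool-adjacent-violators fit,
#' since multiple independent errors on one molecule are rarer than single
#' ones.
#'
#' @param profiles Tibble of per-sample profiles: `sample_id`, `locus_id`,
#'   `allele`, `count`.
#' @param panel Optional panel tibble; loci absent from `profiles` then get
#'   unusable (`usable = FALSE`) floor-rate entries.
#' @param hom_alpha Second-allele acceptance ratio (default 0.05).
#' @param floor_rate Pseudo-rate for unobserved mismatch counts
#'   (default 1e-6), also the lower bound of every estimate so downstream
#'   binomial tests are defined.
#' @param isotonic Apply the non-increasing adjustment (default TRUE).
#' @return An `msmix_error_profile` tibble: `locus_id`, `n`, `e_rate`,
#'   `n_samples`, `usable`. The `floor_rate` is carried as an attribute.
#' @export
estimate_error_profile <- function(profiles, panel = NULL, hom_alpha = 0.05,
                                   floor_rate = 1e-6, isotonic = TRUE) {
  stopifnot(all(c("sample_id", "locus_id", "allele", "count") %in%
                  names(profiles)))
  pr <- profiles %>%
    filter(.data$count > 0) %>%
    arrange(.data$sample_id, .data$locus_id, desc(.data$count), .data$allele)
  if (nrow(pr) == 0L) abort("estimate_error_profile(): no reads in profiles")

  key <- paste(pr$sample_id, pr$locus_id, sep = "\r")
  new_grp <- c(TRUE, key[-1L] != key[-length(key)])
  grp <- cumsum(new_grp)
  rank_in_grp <- sequence(rle(grp)$lengths)
  n_grp <- grp[length(grp)]

  top1 <- pr$allele[new_grp]        # per group
  top1_count <- pr$count[new_grp]   # per group
  second_idx <- which(rank_in_grp == 2L)
  sec_allele <- rep(NA_character_, n_grp)
  sec_count <- rep(0, n_grp)
  sec_allele[grp[second_idx]] <- pr$allele[second_idx]
  sec_count[grp[second_idx]] <- pr$count[second_idx]
  third_count <- rep(0, n_grp)
  third_idx <- which(rank_in_grp == 3L)
  third_count[grp[third_idx]] <- pr$count[third_idx]
  # second allele is true iff it clears the homozygote ratio and is not tied
  # with third place
  sec_true <- !is.na(sec_allele) &
    sec_count >= hom_alpha * top1_count &
    sec_count > third_count

  is_true <- rank_in_grp == 1L | (rank_in_grp == 2L & sec_true[grp])
  err <- !is_true
  d1 <- hamming(pr$allele[err], top1[grp[err]])
  n_err <- d1
  has_sec <- sec_true[grp][err]
  if (any(has_sec)) {
    d2 <- hamming(pr$allele[err][has_sec], sec_allele[grp][err][has_sec])
    n_err[has_sec] <- pmin(d1[has_sec], d2)
  }

  totals <- rowsum(pr$count, grp)[, 1]
  err_tab <- tibble(
    sample_id = pr$sample_id[err], locus_id = pr$locus_id[err],
    n = n_err, frac = pr$count[err] / totals[grp[err]]
  ) %>%
    group_by(.data$sample_id, .data$locus_id, .data$n) %>%
    summarise(frac = sum(.data$frac), .groups = "drop")

  locus_len <- pr %>%
    group_by(.data$locus_id) %>%
    summarise(s = nchar(.data$allele[1]),
              n_samples = n_distinct(.data$sample_id), .groups = "drop")

  grid <- locus_len %>%
    mutate(n = lapply(.data$s, seq_len)) %>%
    tidyr::unnest("n") %>%
    left_join(
      err_tab %>% group_by(.data$locus_id, .data$n) %>%
        summarise(sum_frac = sum(.data$frac), .groups = "drop"),
      by = c("locus_id", "n")
    ) %>%
    mutate(
      e_rate = pmax(dplyr::coalesce(.data$sum_frac, 0) / .data$n_samples,
                    floor_rate),
      usable = TRUE
    )
  if (isotonic) {
    grid <- grid %>%
      group_by(.data$locus_id) %>%
      arrange(.data$n, .by_group = TRUE) %>%
      mutate(e_rate = pava_nonincreasing(.data$e_rate)) %>%
      ungroup()
  }
  out <- grid %>% select("locus_id", "n", "e_rate", "n_samples", "usable")

  if (!is.null(panel)) {
    missing <- setdiff(panel$locus_id, out$locus_id)
    if (length(missing) > 0L) {
      add <- panel %>%
        filter(.data$locus_id %in% missing) %>%
        mutate(n = lapply(.data$n_snps, seq_len)) %>%
        select("locus_id", "n") %>%
        tidyr::unnest("n") %>%
        mutate(e_rate = floor_rate, n_samples = 0L, usable = FALSE)
      out <- bind_rows(out, add)
    }
  }
  out <- arrange(out, .data$locus_id, .data$n)
  out <- msmix_tbl(out, "msmix_error_profile")
  attr(out, "floor_rate") <- floor_rate
  out
}

#' Per-sample artifact read fractions at one locus
#'
#' The per-sample quantity averaged by [estimate_error_profile()]: for one
#' sample's profile at one locus, the fraction of retained reads carried by
#' artifact alleles at each mismatch count. Mostly a building block for
#' inspection and tests.
#'
#' @param alleles,counts Allele strings and read-pair counts of one sample at
#'   one locus.
#' @inheritParams estimate_error_profile
#' @return A tibble `n`, `ratio`.
#' @export
error_read_ratios <- function(alleles, counts, hom_alpha = 0.05) {
  ord <- order(-counts, alleles)
  alleles <- alleles[ord]
  counts <- counts[ord]
  total <- sum(counts)
  truth <- alleles[1]
  if (length(alleles) >= 2L && counts[2] >= hom_alpha * counts[1] &&
      (length(alleles) < 3L || counts[2] > counts[3])) {
    truth <- alleles[1:2]
  }
  err <- setdiff(seq_along(alleles), seq_along(truth))
  if (length(err) == 0L) return(tibble(n = integer(), ratio = numeric()))
  nt <- nearest_template(alleles[err], truth)
  tibble(n = nt$n, count = counts[err]) %>%
    group_by(.data$n) %>%
    summarise(ratio = sum(.data$count) / total, .groups = "drop")
}

#' Write / read an error-profile TSV
#'
#' @param error_profile An `msmix_error_profile` tibble.
#' @param path Output path.
#' @export
write_error_profile <- function(error_profile, path) {
  d <- as.data.frame(error_profile)
  attr_floor <- attr(error_profile, "floor_rate") %||% 1e-6
  d$floor_rate <- attr_floor
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_error_profile
#' @export
read_error_profile <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  out <- msmix_tbl(as_tibble(d[, c("locus_id", "n", "e_rate", "n_samples",
                                   "usable")]), "msmix_error_profile")
  attr(out, "floor_rate") <- d$floor_rate[1]
  out
}
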