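# Mixture scoring: detection rates and minor-allele distinguishability.

# Canonical (locus, allele) sets.
called_set <- function(calls) {
  distinct(true_alleles(calls), .data$locus_id, .data$allele)
}

truth_set <- function(truth) {
  distinct(truth, .data$locus_id, .data$allele)
}

#' Overall detection rate of a call set against known contributors
#'
#' The ratio of the number of detected alleles that match the union of the
#' contributors' true alleles to the total number of alleles detected.
#' Alleles are counted as unique allele strings per locus (not read
#' weighted); loci with no calls contribute nothing.
#'
#' @param calls An `msmix_calls` tibble (major + minor alleles are the
#'   detected set).
#' @param truth Tibble of true alleles with columns `locus_id`, `allele`
#'   (union over contributors; a `contributor` column is allowed and
#'   ignored).
#' @return The detection rate in `[0, 1]`; `NA` (with a warning) when
#'   nothing was detected.
#' @export
detection_rate <- function(calls, truth) {
  det <- called_set(calls)
  if (nrow(det) == 0L) {
    warn("detection_rate(): empty call set; rate undefined")
    return(NA_real_)
  }
  tr <- truth_set(truth)
  matched <- nrow(semi_join(det, tr, by = c("locus_id", "allele")))
  matched / nrow(det)
}

#' Per-contributor detection rate
#'
#' The fraction of one contributor's true alleles -- over the loci the call
#' set attempted (i.e. loci with at least one call) -- that appear among the
#' called alleles.
#'
#' @param calls An `msmix_calls` tibble.
#' @param contributor_truth Tibble of the contributor's alleles: `locus_id`,
#'   `allele`.
#' @return Fraction in `[0, 1]`; `NA` if no truth allele lies on an
#'   attempted locus.
#' @export
contributor_detection <- function(calls, contributor_truth) {
  det <- called_set(calls)
  tr <- truth_set(contributor_truth) %>%
    filter(.data$locus_id %in% unique(det$locus_id))
  if (nrow(tr) == 0L) return(NA_real_)
  nrow(semi_join(tr, det, by = c("locus_id", "allele"))) / nrow(tr)
}

#' Minor-contributor allele distinguishability
#'
#' Restricted to the minor contributor's *unique* alleles -- alleles of the
#' minor that no other contributor carries at that locus -- the fraction that
#' the caller recovered. These are the alleles that prove the presence of
#' the minor contributor in the mixture.
#'
#' @param calls An `msmix_calls` tibble for the mixture.
#' @param truth Tibble of all contributors' alleles: `contributor`,
#'   `locus_id`, `allele`.
#' @param minor_id The minor contributor's identifier in `truth`.
#' @return A one-row tibble: `minor_id`, `n_unique` (minor-unique alleles on
#'   attempted loci), `n_called`, `rate`. `rate` is `NA` (with a warning)
#'   when the minor has no unique alleles.
#' @export
minor_distinguishability <- function(calls, truth, minor_id) {
  stopifnot(all(c("contributor", "locus_id", "allele") %in% names(truth)))
  if (!minor_id %in% truth$contributor) {
    abort("minor_distinguishability(): minor_id not among contributors")
  }
  det <- called_set(calls)
  others <- truth %>%
    filter(.data$contributor != minor_id) %>%
    distinct(.data$locus_id, .data$allele)
  uniq <- truth %>%
    filter(.data$contributor == minor_id) %>%
    distinct(.data$locus_id, .data$allele) %>%
    anti_join(others, by = c("locus_id", "allele")) %>%
    filter(.data$locus_id %in% unique(det$locus_id))
  if (nrow(uniq) == 0L) {
    warn("minor_distinguishability(): minor has no unique alleles; undefined")
    return(tibble(minor_id = minor_id, n_unique = 0L, n_called = 0L,
                  rate = NA_real_))
  }
  n_called <- nrow(semi_join(uniq, det, by = c("locus_id", "allele")))
  tibble(minor_id = minor_id, n_unique = nrow(uniq),
         n_called = n_called, rate = n_called / nrow(uniq))
}

#' Full mixture report
#'
#' Bundles the overall detection rate, per-contributor detection rates,
#' optional minor-allele distinguishability and a per-locus match table for
#' one mixture experiment.
#'
#' @inheritParams minor_distinguishability
#' @param minor_id Optional minor contributor id; adds the
#'   distinguishability block when given.
#' @return A list of class `msmix_mixture_report` with elements `summary`
#'   (one-row tibble), `per_contributor`, `minor` (or `NULL`) and
#'   `per_locus` (called alleles joined with their truth status).
#' @export
mixture_report <- function(calls, truth, minor_id = NULL) {
  det <- called_set(calls)
  tr <- truth_set(truth)
  per_locus <- det %>%
    mutate(in_truth = paste(.data$locus_id, .data$allele) %in%
             paste(tr$locus_id, tr$allele))
  per_contrib <- truth %>%
    distinct(.data$contributor) %>%
    mutate(rate = vapply(.data$contributor, function(cid) {
      contributor_detection(calls,
                            filter(truth, .data$contributor == cid))
    }, numeric(1)))
  minor <- if (!is.null(minor_id)) {
    minor_distinguishability(calls, truth, minor_id)
  }
  out <- list(
    summary = tibble(
      n_loci_attempted = dplyr::n_distinct(det$locus_id),
      n_alleles_detected = nrow(det),
      detection_rate = detection_rate(calls, truth),
      minor_distinguishability = if (is.null(minor)) NA_real_ else minor$rate
    ),
    per_contributor = per_contrib,
    minor = minor,
    per_locus = per_locus
  )
  class(out) <- "msmix_mixture_report"
  out
}

#' @export
print.msmix_mixture_report <- function(x, ...) {
  cat("Mixture report\n")
  cat(sprintf("  loci attempted: %d, alleles detected: %d\n",
              x$summary$n_loci_attempted, x$summary$n_alleles_detected))
  cat(sprintf("  overall detection rate: %.4f\n", x$summary$detection_rate))
  for (i in seq_len(nrow(x$per_contributor))) {
    cat(sprintf("  contributor %s: %.4f\n",
                x$per_contributor$contributor[i], x$per_contributor$rate[i]))
  }
  if (!is.null(x$minor) && !is.na(x$minor$rate)) {
    cat(sprintf("  minor-unique alleles called: %d/%d (%.1f%%)\n",
                x$minor$n_called, x$minor$n_unique, 100 * x$minor$rate))
  }
  invisible(x)
}
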