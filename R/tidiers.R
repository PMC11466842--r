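# broom-style tidy()/glance() methods for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an allele call set
#'
#' @param x An `msmix_calls` tibble.
#' @param ... Unused.
#' @return The calls as a plain tibble, one row per tested allele.
#' @export
tidy.msmix_calls <- function(x, ...) {
  as_tibble(unclass_msmix(x))
}

#' @rdname tidy.msmix_calls
#' @return For `glance()`: a one-row summary with locus and allele tallies.
#' @export
glance.msmix_calls <- function(x, ...) {
  tibble(
    n_loci = dplyr::n_distinct(x$locus_id),
    n_alleles_tested = nrow(x),
    n_major = sum(x$status == "major"),
    n_minor = sum(x$status == "minor"),
    n_artifact = sum(x$status == "artifact"),
    max_iteration = max(c(0L, x$iteration), na.rm = TRUE)
  )
}

#' Tidy an error profile
#'
#' @param x An `msmix_error_profile` tibble.
#' @param ... Unused.
#' @return The profile as a plain tibble (`locus_id`, `n`, `e_rate`, ...).
#' @export
tidy.msmix_error_profile <- function(x, ...) {
  as_tibble(unclass_msmix(x))
}

#' @rdname tidy.msmix_error_profile
#' @return For `glance()`: a one-row summary of the profile.
#' @export
glance.msmix_error_profile <- function(x, ...) {
  tibble(
    n_loci = dplyr::n_distinct(x$locus_id),
    n_usable = dplyr::n_distinct(x$locus_id[x$usable]),
    mean_e1 = mean(x$e_rate[x$n == 1]),
    floor_rate = attr(x, "floor_rate") %||% NA_real_
  )
}

#' Tidy per-locus forensic statistics
#'
#' @param x An `msmix_locus_stats` tibble.
#' @param ... Unused.
#' @return The per-locus statistics without the frequency list column.
#' @export
tidy.msmix_locus_stats <- function(x, ...) {
  select(as_tibble(unclass_msmix(x)), -"allele_freqs")
}

#' @rdname tidy.msmix_locus_stats
#' @param family_alpha Family-wise HWE level for [combine_panel()].
#' @return For `glance()`: the combined panel statistics.
#' @export
glance.msmix_locus_stats <- function(x, family_alpha = 0.05, ...) {
  combine_panel(x, family_alpha = family_alpha)
}

unclass_msmix <- function(x) {
  class(x) <- class(tibble())
  x
}
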