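# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an error profile
#'
#' One line per locus: the estimated artifact read fraction `e_l(n)` against
#' the mismatch count `n`, on a log scale, with the across-loci median
#' highlighted.
#'
#' @param object An `msmix_error_profile` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.msmix_error_profile <- function(object, ...) {
  d <- as_tibble(unclass_msmix(object))
  med <- d %>%
    group_by(.data$n) %>%
    summarise(e_rate = stats::median(.data$e_rate), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n, y = .data$e_rate)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$locus_id),
                       alpha = 0.15, colour = "grey40") +
    ggplot2::geom_line(data = med, colour = "firebrick", linewidth = 1) +
    ggplot2::geom_point(data = med, colour = "firebrick") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "mismatches to template (n)",
                  y = expression(e[l](n)),
                  title = "Locus error profiles",
                  subtitle = "grey: loci; red: panel median") +
    ggplot2::theme_minimal()
}

#' Plot an allele call set
#'
#' Read counts per allele for the most allele-rich loci, coloured by call
#' status, on a log scale. Shows how the accepted minors separate from the
#' artifact cloud.
#'
#' @param object An `msmix_calls` tibble.
#' @param loci Locus ids to show; default picks the 12 with most alleles.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.msmix_calls <- function(object, loci = NULL, ...) {
  d <- as_tibble(unclass_msmix(object))
  if (is.null(loci)) {
    loci <- d %>%
      count(.data$locus_id) %>%
      arrange(desc(.data$n)) %>%
      head(12) %>%
      pull(.data$locus_id)
  }
  d <- filter(d, .data$locus_id %in% loci)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$allele, y = .data$count,
                                  fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~locus_id, scales = "free_x") +
    ggplot2::scale_fill_manual(values = c(major = "#1b7837",
                                          minor = "#5aae61",
                                          artifact = "grey60")) +
    ggplot2::labs(x = NULL, y = "concordant read pairs",
                  title = "Allele calls") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}

#' Plot per-locus forensic statistics
#'
#' Observed vs expected heterozygosity per locus, sized by discrimination
#' power, with the diagonal as reference.
#'
#' @param object An `msmix_locus_stats` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.msmix_locus_stats <- function(object, ...) {
  d <- tidy.msmix_locus_stats(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$He, y = .data$Ho,
                                  size = .data$DP)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.5, colour = "#2166ac") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "expected heterozygosity (He)",
                  y = "observed heterozygosity (Ho)",
                  size = "DP",
                  title = "Per-locus heterozygosity") +
    ggplot2::theme_minimal()
}

#' Detection rates of a set of mixture reports
#'
#' Column plot of per-contributor detection rates across mixtures.
#'
#' @param reports A tibble binding `per_contributor` blocks of
#'   [mixture_report()] results, with an added `mixture` column.
#' @return A ggplot.
#' @export
plot_detection_rates <- function(reports) {
  ggplot2::ggplot(reports,
                  ggplot2::aes(x = .data$mixture, y = .data$rate,
                               fill = .data$contributor)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "detection rate",
                  title = "Per-contributor detection rates") +
    ggplot2::theme_minimal()
}
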