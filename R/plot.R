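# ggplot2 views of the main result types.

#' Plot the SV classification spectrum
#'
#' Stacked bars of locus counts per category, split by the number of
#' distinct alleles (biallelic / triallelic / multiallelic).
#'
#' @param object A `canisv_classification_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.canisv_classification_summary <- function(object, ...) {
  df <- object$by_category
  df$category <- factor(df$category, levels = SV_CATEGORIES)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$n,
                                   fill = .data$allele_count_class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "loci", fill = "alleles") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot the SV size-difference spectrum
#'
#' Histogram (log-spaced bins) of the size difference between the largest
#' and smallest allele per locus; peaks near 200 bp and 6 kb reflect SINEC
#' and LINE-1 insertions.
#'
#' @param summary A `canisv_classification_summary`.
#' @return A ggplot.
#' @export
plot_size_spectrum <- function(summary) {
  df <- summary$size_histogram
  ggplot2::ggplot(df, ggplot2::aes(x = sqrt(.data$bin_lo * .data$bin_hi),
                                   y = .data$n)) +
    ggplot2::geom_col(width = 0.08) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "size difference (bp)", y = "loci") +
    ggplot2::theme_minimal()
}

#' Plot per-sample MEI sharing and zygosity
#'
#' @param object A `canisv_sharing` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.canisv_sharing <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_sample,
                            cols = c("n_het", "n_hom", "n_singleton"),
                            names_to = "measure", values_to = "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$n,
                                   fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "loci", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-comparison insertion-rate estimates
#'
#' @param object A `canisv_rates` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.canisv_rates <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$rate)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$mean_rate, linetype = 2) +
    ggplot2::labs(x = NULL, y = "insertions per generation",
                  title = paste0(object$element_type,
                                 " insertion rate (mean ~1/",
                                 object$mean_rate_reciprocal, " births)")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot STR enrichment folds
#'
#' Observed/expected fold per annotation class with the permutation null
#' at fold = 1.
#'
#' @param object A `canisv_enrichment` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.canisv_enrichment <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class_name, y = .data$fold)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = NULL, y = "fold enrichment") +
    ggplot2::theme_minimal()
}
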