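# ggplot2 views of the main result types.

#' Plot per-source closure counts
#'
#' @param summary a [summarize_closures()] tibble.
#' @return a ggplot.
#' @export
plot_closure_summary <- function(summary) {
  df <- dplyr::filter(summary, .data$source != "Total")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$source, y = .data$n_closed)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "filler source", y = "gaps closed",
                  title = "Gap closures by source") +
    ggplot2::theme_minimal()
}

#' Plot the lost-gene density profile along the arm
#'
#' @param profile a [loss_density_profile()] tibble.
#' @return a ggplot.
#' @export
plot_loss_density <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = (.data$bin_start + .data$bin_end) / 2e6,
                               y = .data$n_lost)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(x = "position (Mb)", y = "lost genes",
                  title = "Gene-loss density along the arm") +
    ggplot2::theme_minimal()
}

#' Histogram of pairwise omega (dN/dS)
#'
#' @param pairs a [ng86_dnds_pairs()] / [classify_selection()] tibble.
#' @param bins histogram bins (default 30).
#' @return a ggplot.
#' @export
plot_omega_distribution <- function(pairs, bins = 30) {
  df <- dplyr::filter(pairs, !is.na(.data$omega))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$omega)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey40") +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "red") +
    ggplot2::labs(x = expression(omega == dN / dS), y = "gene pairs",
                  title = "Selection scan") +
    ggplot2::theme_minimal()
}

#' Heat map of the feature correlation matrix
#'
#' Non-significant cells (p >= alpha) are blanked.
#'
#' @param object a [feature_correlation()] object.
#' @param alpha significance cut-off for display (default 0.05).
#' @param ... unused.
#' @return a ggplot.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.feature_correlation <- function(object, alpha = 0.05, ...) {
  x <- object
  df <- tidy(x)
  df$rho[!is.na(df$p) & df$p >= alpha] <- NA
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature_a, y = .data$feature_b,
                                   fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-1, 1), na.value = "grey95") +
    ggplot2::labs(x = NULL, y = NULL, fill = "rho",
                  title = "Spearman correlation of gene features") +
    ggplot2::theme_minimal()
}

#' Histogram of LTR insertion ages
#'
#' @param ages a [date_ltr_cohort()] tibble.
#' @param bins histogram bins (default 30).
#' @return a ggplot.
#' @export
plot_ltr_ages <- function(ages, bins = 30) {
  ggplot2::ggplot(ages, ggplot2::aes(x = .data$T_years / 1e6)) +
    ggplot2::geom_histogram(bins = bins, fill = "darkgreen") +
    ggplot2::labs(x = "insertion age (MYA)", y = "elements",
                  title = "LTR insertion ages") +
    ggplot2::theme_minimal()
}
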