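# ggplot2 helpers for scan results.

#' Plot a windowed F_ST track with divergent regions highlighted
#'
#' @param stats Window statistics tibble.
#' @param regions Optional region tibble from [link_windows()] to shade.
#' @param fst_col F_ST column name (default first `fst_*` column).
#' @return A ggplot object.
#' @export
plot_fst_track <- function(stats, regions = NULL, fst_col = NULL) {
  if (is.null(fst_col)) {
    fst_col <- grep("^fst", names(stats), value = TRUE)[1]
  }
  p <- ggplot2::ggplot(stats,
                       ggplot2::aes(x = (.data$start + .data$end) / 2,
                                    y = .data[[fst_col]])) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::facet_wrap(~scaffold, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = expression(F[ST])) +
    ggplot2::theme_minimal()
  if (!is.null(regions) && nrow(regions) > 0) {
    p <- p + ggplot2::geom_rect(
      data = regions,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, fill = "firebrick", alpha = 0.2,
      inherit.aes = FALSE)
  }
  p
}

#' Bar plot of divergent-vs-background comparisons with bootstrap CIs
#'
#' Mirrors the divergent-region/background panel layout: one facet per
#' statistic, bars for group means, error bars for the bootstrap 95% CIs.
#'
#' @param comparisons Comparison tibble from [run_full()] (rows from
#'   [bootstrap_compare()]).
#' @return A ggplot object.
#' @export
plot_group_comparison <- function(comparisons) {
  long <- dplyr::bind_rows(
    tibble::tibble(statistic = comparisons$statistic, group = "divergent",
                   mean = comparisons$mean_in, lo = comparisons$ci_low_in,
                   hi = comparisons$ci_high_in),
    tibble::tibble(statistic = comparisons$statistic, group = "background",
                   mean = comparisons$mean_out, lo = comparisons$ci_low_out,
                   hi = comparisons$ci_high_out))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$mean,
                                     fill = .data$group)) +
    ggplot2::geom_col(width = 0.6, show.legend = FALSE) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           width = 0.2) +
    ggplot2::scale_fill_manual(values = c(divergent = "white",
                                          background = "grey60")) +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean (95% bootstrap CI)") +
    ggplot2::theme_bw()
}

#' Density plot of simulated F_ST distributions with and without migration
#'
#' @param x A `divscan_fst_comparison` from [fst_distribution_comparison()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot divscan_fst_comparison
#' @export
autoplot.divscan_fst_comparison <- function(x, ...) {
  ggplot2::ggplot(dplyr::filter(x$per_locus, !is.na(.data$fst)),
                  ggplot2::aes(x = .data$fst, fill = .data$model)) +
    ggplot2::geom_density(alpha = 0.4, colour = NA) +
    ggplot2::facet_wrap(~pair) +
    ggplot2::labs(x = expression(F[ST]), y = "density", fill = NULL) +
    ggplot2::theme_minimal()
}
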