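#' Overlayed feature histograms of two phase-space tables
#'
#' Normalized histograms of the six phase-space features for one or two
#' tables, faceted per feature — the standard visual check that a
#' surrogate's marginals track the simulator's.
#'
#' @param table_a First phase-space table.
#' @param table_b Optional second table to overlay.
#' @param labels Character vector of length 2 naming the tables.
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_phase_space <- function(table_a, table_b = NULL,
                             labels = c("simulated", "generated"),
                             bins = 100) {
  feats <- phase_space_columns[1:6]
  stack <- function(tb, lab) {
    tidyr::pivot_longer(
      dplyr::mutate(tb[feats], source = lab),
      cols = dplyr::all_of(feats),
      names_to = "feature", values_to = "value"
    )
  }
  long <- stack(tibble::as_tibble(table_a), labels[1])
  if (!is.null(table_b)) {
    long <- dplyr::bind_rows(long, stack(tibble::as_tibble(table_b), labels[2]))
  }
  long$feature <- factor(long$feature, levels = feats)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value,
                                     y = ggplot2::after_stat(.data$density),
                                     colour = .data$source)) +
    ggplot2::geom_freqpoly(bins = bins, linewidth = 0.4) +
    ggplot2::facet_wrap(~feature, scales = "free") +
    ggplot2::labs(x = NULL, y = "density", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a similarity report
#'
#' Per-feature `1 - JSD` similarity as a bar chart.
#'
#' @param object A [similarity_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot similarity_report
#' @export
autoplot.similarity_report <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object))
  df$feature <- factor(df$feature, levels = df$feature)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature, y = 100 * .data$similarity)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(min(80, floor(100 * min(df$similarity))), 100)) +
    ggplot2::labs(x = NULL, y = "similarity (%)") +
    ggplot2::theme_minimal()
}

#' Plot a training log
#'
#' Losses and checkpoint similarity per epoch.
#'
#' @param object A `gan_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gan_fit
#' @export
autoplot.gan_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$log, cols = -"epoch",
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
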