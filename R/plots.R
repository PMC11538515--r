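#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot methods for result objects
#'
#' `autoplot.transtox_fit()` draws the training loss trajectories;
#' `autoplot.agreement_report()` the synthetic-vs-negative-control violin
#' comparison per metric; `autoplot.gene_variability()` the histogram of
#' gene-level variability per statistic; [plot_overlap_ratios()] the
#' overlap-ratio violins by dose or time; [plot_embedding()] a 2-D
#' embedding coloured by label.
#'
#' @param object The result object.
#' @param ... Unused.
#' @return A ggplot.
#' @name organxlate-plots
NULL

#' @rdname organxlate-plots
#' @export
autoplot.transtox_fit <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$epoch, y = .data$value,
                               colour = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "loss (log scale)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname organxlate-plots
#' @export
autoplot.agreement_report <- function(object, ...) {
  synth <- tidyr::pivot_longer(object$per_pair, -"sample_id",
                               names_to = "metric", values_to = "value")
  synth$group <- "synthetic"
  base <- object$baseline[c("metric", "value")]
  base$group <- "negative control"
  df <- dplyr::bind_rows(synth[c("metric", "value", "group")], base)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$value,
                                   fill = .data$group)) +
    ggplot2::geom_violin(show.legend = FALSE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste0("Synthetic vs negative control (",
                                 object$organ, ")")) +
    ggplot2::theme_minimal()
}

#' @rdname organxlate-plots
#' @export
autoplot.gene_variability <- function(object, ...) {
  ggplot2::ggplot(object$values, ggplot2::aes(x = .data$v)) +
    ggplot2::geom_histogram(bins = 60) +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::coord_cartesian(xlim = c(-0.5, 0.5)) +
    ggplot2::labs(x = "normalised difference", y = "gene-treatment pairs") +
    ggplot2::theme_minimal()
}

#' @rdname organxlate-plots
#' @param overlaps Tibble from [deg_concordance()] or
#'   [subgroup_replication()].
#' @param by Grouping variable on the x axis (`"dose"` or `"time_days"`).
#' @export
plot_overlap_ratios <- function(overlaps, by = c("dose", "time_days")) {
  by <- match.arg(by)
  ggplot2::ggplot(overlaps,
                  ggplot2::aes(x = factor(.data[[by]]), y = .data$overlap)) +
    ggplot2::geom_violin(fill = "grey80") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5, size = 0.8) +
    ggplot2::facet_wrap(~type) +
    ggplot2::labs(x = by, y = "overlap ratio") +
    ggplot2::theme_minimal()
}

#' @rdname organxlate-plots
#' @param embedding Tibble from [embed_2d()].
#' @export
plot_embedding <- function(embedding) {
  ggplot2::ggplot(embedding, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                          colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "dim 1", y = "dim 2", colour = NULL) +
    ggplot2::theme_minimal()
}
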