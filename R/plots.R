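# ggplot2 renderings of the result tables.

#' Forest plot of a PRR screen
#'
#' Point estimates with confidence intervals on a log scale; flagged
#' signals are highlighted and the threshold drawn as a dashed line.
#'
#' @param object A `prr_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.prr_table <- function(object, ...) {
  threshold <- attr(object, "threshold") %||% 2
  df <- as_tibble(object) %>%
    filter(!is.na(.data$prr), .data$prr > 0) %>%
    mutate(group = stats::reorder(.data$group, .data$prr))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$prr, y = .data$group)) +
    ggplot2::geom_vline(xintercept = 1, colour = "grey70") +
    ggplot2::geom_vline(
      xintercept = threshold, linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      height = 0.25, colour = "grey50", na.rm = TRUE
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$signal), size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#c0392b", `FALSE` = "#2c3e50"),
      labels = c(`TRUE` = "signal", `FALSE` = "no signal"), name = NULL
    ) +
    ggplot2::labs(
      x = "Proportional reporting ratio (log scale)", y = NULL,
      title = "Disproportionate reporting by adverse-event group"
    ) +
    ggplot2::theme_minimal()
}

#' @export
plot.prr_table <- function(x, ...) print(autoplot.prr_table(x, ...))

#' Bar chart of stratified incidence rates
#'
#' @param table Incidence tibble from [build_incidence_table()].
#' @param axis Stratum axis to display (default the first non-TOTAL axis
#'   present).
#' @return A ggplot object.
#' @export
plot_incidence <- function(table, axis = NULL) {
  axes_present <- setdiff(unique(table$axis), "TOTAL")
  axis <- axis %||% axes_present[1]
  df <- table %>%
    filter(.data$axis == !!axis, .data$group != ANY_GROUP) %>%
    mutate(group = stats::reorder(.data$group, .data$ir_per_100k))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$ir_per_100k, y = .data$group, fill = .data$level
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$series), scales = "free_x") +
    ggplot2::labs(
      x = "Reports per 100,000 vaccinated persons", y = NULL,
      fill = axis,
      title = sprintf("Incidence of adverse-event groups by %s", tolower(axis))
    ) +
    ggplot2::theme_minimal()
}
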