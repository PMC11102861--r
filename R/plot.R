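#' Heatmap of a deadenylation time course
#'
#' Species position on the vertical axis (position 1, the intact substrate,
#' at the top), reaction time on the horizontal, viridis fill. Heatmaps are
#' drawn from column-normalized data so the dominant species at each time
#' stands out; unnormalized input is column-normalized automatically with a
#' notice.
#'
#' @param tc A time-course tibble.
#' @param path Optional file path; if given the plot is also saved with
#'   [ggplot2::ggsave()] (format from the extension).
#' @param width,height Device size in inches when saving.
#' @return A ggplot object (invisibly when `path` is given).
#' @export
plot_heatmap <- function(tc, path = NULL, width = 5, height = 4) {
  validate_time_course(tc)
  col_max <- apply(tc_values(tc), 2, max)
  if (any(abs(col_max[col_max > 0] - 1) > 1e-8)) {
    inform("Input is not column-normalized; applying normalize_columns() for display.")
    tc <- normalize_columns(tc)
  }
  long <- tc_longer(tc)
  p <- ggplot2::ggplot(long, ggplot2::aes(
    x = factor(.data$time, levels = sort(unique(.data$time))),
    y = .data$position, fill = .data$abundance
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse(breaks = unique(long$position)) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "relative\nintensity") +
    ggplot2::labs(x = "time (min)", y = "position from 3' end") +
    ggplot2::theme_minimal()
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = width, height = height)
    return(invisible(p))
  }
  p
}

#' Plot a per-position rate profile
#'
#' Rates (nt/min) against tail position from the 3' end, with `+/- 1 se`
#' error bars when available.
#'
#' @param rates A rate tibble (`position`, `lambda`, optionally `se`).
#' @return A ggplot object.
#' @export
plot_rate_profile <- function(rates) {
  stopifnot(all(c("position", "lambda") %in% names(rates)))
  p <- ggplot2::ggplot(rates, ggplot2::aes(x = .data$position, y = .data$lambda)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "position from 3' end",
      y = expression(paste("removal rate ", lambda, " (nt ", min^-1, ")"))
    ) +
    ggplot2::theme_minimal()
  if ("se" %in% names(rates) && any(!is.na(rates$se))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$lambda - .data$se, ymax = .data$lambda + .data$se),
      width = 0.3, na.rm = TRUE
    )
  }
  p
}

#' @rdname plot_rate_profile
#' @param object A `deadenylation_fit`.
#' @param ... Unused.
#' @method autoplot deadenylation_fit
#' @export
autoplot.deadenylation_fit <- function(object, ...) {
  plot_rate_profile(object$rates)
}

#' @rdname plot_heatmap
#' @param object,... For the autoplot methods.
#' @method autoplot deadenylation_scenario
#' @export
autoplot.deadenylation_scenario <- function(object, ...) {
  plot_rate_profile(make_rate_profile(object))
}
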