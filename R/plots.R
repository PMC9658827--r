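# ggplot2 views of distance series and run reports

#' Plot per-residue COM distance traces
#'
#' One line per residue of the per-frame center-of-mass distance to the
#' closest partner residue, with optional horizontal reference at the COM
#' threshold.
#'
#' @param series Distance-series tibble from [com_distance_series()] or the
#'   `$series` of a `replicate_contacts` object.
#' @param residues Optional character vector restricting which residue
#'   labels are drawn.
#' @param com_threshold Optional reference distance (Angstroms) drawn as a
#'   dashed line.
#' @return A ggplot object.
#' @export
plot_distance_series <- function(series, residues = NULL, com_threshold = NULL) {
  if (!is.null(residues)) series <- series[series$residue %in% residues, ]
  p <- ggplot2::ggplot(series,
                       ggplot2::aes(x = .data$frame, y = .data$distance,
                                    colour = .data$residue)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "frame", y = "COM distance to closest partner residue (\u00c5)",
                  colour = "residue") +
    ggplot2::theme_minimal()
  if (!is.null(com_threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = com_threshold, linetype = "dashed")
  }
  if ("replicate_id" %in% names(series) &&
      length(unique(series$replicate_id)) > 1) {
    p <- p + ggplot2::facet_wrap(~replicate_id)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname plot_distance_series
#' @param object A `replicate_contacts` or `contact_run` object.
#' @param ... Passed to [plot_distance_series()].
#' @method autoplot replicate_contacts
#' @export
autoplot.replicate_contacts <- function(object, ...) {
  plot_distance_series(object$series,
                       com_threshold = object$criteria$com_distance_threshold,
                       ...) +
    ggplot2::ggtitle(sprintf("replicate %s", object$replicate_id))
}

#' @rdname plot_distance_series
#' @method autoplot contact_run
#' @export
autoplot.contact_run <- function(object, ...) {
  d <- object$distances
  d$residue <- factor(d$residue, levels = rev(d$residue))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_distance, y = .data$residue)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$mean_distance - .data$sd_distance,
                   xmax = .data$mean_distance + .data$sd_distance,
                   colour = factor(.data$n_pass))
    ) +
    ggplot2::labs(x = "pooled COM distance (\u00c5)", y = NULL,
                  colour = "replicates\npassing") +
    ggplot2::theme_minimal()
}
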