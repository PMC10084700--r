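#' Actogram of a chick's multichannel recording
#'
#' Stacked panels of ODBA, on-body and ambient temperature, light level
#' (log10) and sun elevation over deployment time, with the detected
#' brooding bouts as shaded polygons across all panels.
#'
#' @param trace 5-s trace tibble.
#' @param bouts Optional finalised bout tibble (brooding bouts drawn).
#' @param title Optional plot title.
#' @return A `ggplot` object.
#' @export
plot_actogram <- function(trace, bouts = NULL, title = NULL) {
  chans <- dplyr::bind_rows(
    tibble::tibble(t_h = trace$t5 / 3600, value = trace$odba5,
                   series = "ODBA", panel = "ODBA (g)"),
    tibble::tibble(t_h = trace$t5 / 3600, value = trace$tbody5,
                   series = "on-body", panel = "temperature (°C)"),
    tibble::tibble(t_h = trace$t5 / 3600, value = trace$tamb5,
                   series = "ambient", panel = "temperature (°C)"),
    tibble::tibble(t_h = trace$t5 / 3600, value = log10(trace$light5 + 1),
                   series = "light", panel = "light (log10 lx)"),
    tibble::tibble(t_h = trace$t5 / 3600, value = trace$sun_elev,
                   series = "sun", panel = "sun elevation (°)"))
  chans$panel <- factor(chans$panel, levels = unique(chans$panel))
  p <- ggplot2::ggplot(chans, ggplot2::aes(x = .data$t_h, y = .data$value,
                                           colour = .data$series))
  if (!is.null(bouts)) {
    bb <- bouts[bouts$label == "brooding", , drop = FALSE]
    if (nrow(bb)) {
      shade <- tibble::tibble(xmin = bb$start_s / 3600, xmax = bb$end_s / 3600)
      p <- p + ggplot2::geom_rect(
        data = shade, inherit.aes = FALSE,
        ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                     ymin = -Inf, ymax = Inf),
        fill = "darkgreen", alpha = 0.15)
    }
  }
  p +
    ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(
      "ODBA" = "darkorange", "on-body" = "firebrick",
      "ambient" = "steelblue", "light" = "black", "sun" = "goldenrod")) +
    ggplot2::labs(x = "time since deployment (h)", y = NULL,
                  colour = NULL, title = title) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(legend.position = "bottom")
}

#' Render an actogram to a file
#'
#' @param trace 5-s trace tibble.
#' @param bouts Finalised bout tibble.
#' @param path Output path (extension selects the graphics device, e.g.
#'   `.pdf` or `.png`).
#' @param width,height Figure size in inches.
#' @return `path`, invisibly.
#' @export
render_actogram <- function(trace, bouts, path, width = 10, height = 7) {
  p <- plot_actogram(trace, bouts,
                     title = attr(trace, "chick_id") %||% NULL)
  ggplot2::ggsave(path, p, width = width, height = height)
  invisible(path)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' EM convergence plot for a fitted two-state HMM
#'
#' @param object A `brood_hmm`.
#' @param ... Unused.
#' @return A `ggplot` of the per-iteration log-likelihood trace.
#' @method autoplot brood_hmm
#' @export
autoplot.brood_hmm <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$loglik_trace),
                       loglik = object$loglik_trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$loglik)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "EM iteration", y = "log-likelihood") +
    ggplot2::theme_minimal()
}
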