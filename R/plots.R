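# ggplot2 graphics for tabs and experiment results.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an annotated tab
#'
#' Draws the walls as segments and the stimulus landmarks, with control
#' stimuli in a lighter shade, in the calibrated after frame. The tab is
#' aligned first if needed.
#'
#' @param object A `comb_tab`.
#' @param ... Unused.
#' @return A ggplot object (y axis reversed to match the image
#'   convention).
#' @method autoplot comb_tab
#' @export
autoplot.comb_tab <- function(object, ...) {
  tab <- align_tab(object)
  lm <- tab$stimuli |>
    dplyr::mutate(pts = purrr::map(.data$landmarks, identity)) |>
    dplyr::select("stimulus_id", "kind", "is_control", "pts") |>
    tidyr::unnest("pts")
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = tab$walls,
      ggplot2::aes(x = .data$x1, y = .data$y1, xend = .data$x2,
                   yend = .data$y2), linewidth = 0.4, colour = "grey40")
  if (nrow(lm) > 0) {
    p <- p + ggplot2::geom_point(data = lm,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$kind,
                   shape = .data$is_control), size = 2)
  }
  p + ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(xlim = c(0, tab$tab_size_mm[1]),
                         ylim = rev(c(0, tab$tab_size_mm[2]))) +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", shape = "control",
                  title = tab$tab_id) +
    ggplot2::theme_minimal()
}

#' Plot the real and control measurement distributions of an experiment
#'
#' Overlaid histograms of each metric's real and control populations,
#' faceted by metric (excluded records are dropped).
#'
#' @param object A `comb_experiment`.
#' @param bins Number of histogram bins (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot comb_experiment
#' @export
autoplot.comb_experiment <- function(object, bins = 20, ...) {
  r <- dplyr::filter(object$records, !.data$excluded,
                     is.finite(.data$value)) |>
    dplyr::mutate(population = ifelse(.data$is_control, "control", "real"))
  ggplot2::ggplot(r, ggplot2::aes(x = .data$value,
                                  fill = .data$population)) +
    ggplot2::geom_histogram(bins = bins, position = "identity",
                            alpha = 0.55) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::scale_fill_manual(values = c(real = "grey15",
                                          control = "grey65")) +
    ggplot2::labs(x = "metric value", y = "count",
                  title = object$experiment) +
    ggplot2::theme_minimal()
}
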