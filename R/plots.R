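#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a synthetic scenario
#'
#' Ground-truth trajectories colored by identity, with detection centers
#' overlaid as translucent points; the y axis is flipped to match image
#' coordinates.
#'
#' @param object An `aquatrack_scenario`.
#' @param show_detections Overlay corrupted detections.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.aquatrack_scenario <- function(object, show_detections = TRUE, ...) {
  p <- ggplot2::ggplot(object$truth, ggplot2::aes(x = .data$cx, y = .data$cy)) +
    ggplot2::geom_path(ggplot2::aes(color = factor(.data$id), group = .data$id)) +
    ggplot2::scale_y_reverse(limits = c(1, 0)) +
    ggplot2::scale_x_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "x (normalized)", y = "y (normalized)", color = "target",
      title = sprintf("synthetic scenario (%s)", object$config$scene)
    ) +
    ggplot2::theme_minimal()
  if (show_detections && nrow(object$detections)) {
    p <- p + ggplot2::geom_point(
      data = object$detections,
      ggplot2::aes(x = .data$cx, y = .data$cy), alpha = 0.15, size = 0.5,
      inherit.aes = FALSE
    )
  }
  p
}

#' Plot tracker output trajectories
#'
#' @param object An `aquatrack_tracks` tibble from [track_sequence()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.aquatrack_tracks <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$cx, y = .data$cy,
    color = factor(.data$id), group = .data$id
  )) +
    ggplot2::geom_path() +
    ggplot2::scale_y_reverse(limits = c(1, 0)) +
    ggplot2::scale_x_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "x (normalized)", y = "y (normalized)", color = "track id") +
    ggplot2::theme_minimal()
}

#' Plot a predictor training curve
#'
#' @param object An `aquatrack_predictor` with a training log.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.aquatrack_predictor <- function(object, ...) {
  stopifnot(!is.null(object$log))
  ggplot2::ggplot(object$log, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "training loss (log scale)") +
    ggplot2::theme_minimal()
}

#' Plot a day/night behavioral rhythm summary
#'
#' Stacked behavior proportions per period, mirroring the usual diurnal
#' rhythm figure.
#'
#' @param rhythm Output of [rhythm_summary()].
#' @return A ggplot object.
#' @export
plot_rhythm <- function(rhythm) {
  dat <- rhythm[rhythm$label != "unclassified", , drop = FALSE]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$period, y = .data$proportion, fill = .data$label)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = NULL, y = "proportion of classified time", fill = "behavior") +
    ggplot2::theme_minimal()
}
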