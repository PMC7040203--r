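#' Speed profile of a trial
#'
#' Plots the grip-centre speed over time with the segmentation threshold and
#' the detected (labelled) movement spans shaded — the standard visual check
#' that the velocity criterion is segmenting a recording sensibly.
#'
#' @param x A [trial()].
#' @param cfg A [segmentation_config()].
#' @return A ggplot object.
#' @export
plot_velocity_profile <- function(x, cfg = segmentation_config()) {
  gc <- grip_center(x)
  speed <- velocity_norm(gc, cfg)
  speed[!is.finite(speed)] <- 0
  d <- tibble::tibble(time_ms = gc$times, speed = speed)
  segs <- tryCatch(
    label_segments(segment_movements(speed, cfg), x),
    error = function(e) NULL)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time_ms, y = .data$speed))
  if (!is.null(segs) && nrow(segs)) {
    shade <- dplyr::mutate(segs,
                           xmin = gc$times[.data$onset],
                           xmax = gc$times[.data$offset])
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax, fill = .data$label),
      ymin = -Inf, ymax = Inf, alpha = 0.15, inherit.aes = FALSE)
  }
  p + ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = cfg$velocity_threshold,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "time (ms)", y = "grip-centre speed (mm/s)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Grip-aperture profile of a trial
#'
#' Thumb-index distance over time; the maximum before contact is the MGA.
#'
#' @param x A [trial()].
#' @return A ggplot object.
#' @export
plot_aperture_profile <- function(x) {
  ap <- aperture_series(x$trajectories$thumb, x$trajectories$index)
  d <- tibble::tibble(time_ms = x$trajectories$thumb$times, aperture = ap)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_ms, y = .data$aperture)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "thumb-index aperture (mm)") +
    ggplot2::theme_minimal()
}

#' Condition means of a feature
#'
#' Mean and standard error of a feature by content and surface, the two
#' object properties the analyses centre on.
#'
#' @param features Feature tibble from [extract_features()].
#' @param dv Feature column name.
#' @return A ggplot object.
#' @export
plot_condition_means <- function(features, dv) {
  d <- features |>
    dplyr::group_by(.data$content, .data$surface) |>
    dplyr::summarise(mean = mean(.data[[dv]], na.rm = TRUE),
                     se = stats::sd(.data[[dv]], na.rm = TRUE) /
                       sqrt(sum(is.finite(.data[[dv]]))),
                     .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$content, y = .data$mean,
                                  colour = .data$surface)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se),
                             position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::labs(x = "content", y = dv, colour = "surface") +
    ggplot2::theme_minimal()
}

coef_plot <- function(table, title) {
  d <- dplyr::filter(table, is.finite(.data$estimate))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$estimate - 1.96 * .data$std.error,
      xmax = .data$estimate + 1.96 * .data$std.error)) +
    ggplot2::labs(x = "estimate (b, with 95% CI)", y = NULL,
                  title = title) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.prehensr_lmm <- function(object, ...) {
  coef_plot(object$table, paste("Linear mixed model:", object$dv))
}

#' @export
autoplot.prehensr_clmm <- function(object, ...) {
  coef_plot(object$table,
            paste("Cumulative-link mixed model:", object$dv))
}

#' @export
autoplot.trial <- function(object, ...) plot_velocity_profile(object, ...)
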