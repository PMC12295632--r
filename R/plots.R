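#' Plot a group locomotor profile
#'
#' Mean distance per time bin with an SEM ribbon; light epochs can be
#' shaded by passing the schedule.
#'
#' @param object A `swim_profile` (rows for one or several groups).
#' @param schedule Optional [light_schedule()]; light epochs are shaded.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot swim_profile
#' @export
autoplot.swim_profile <- function(object, schedule = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_mid_s,
                                            y = .data$mean_distance_mm,
                                            colour = .data$group,
                                            fill = .data$group))
  if (!is.null(schedule)) {
    light <- schedule[schedule$condition == "light", ]
    p <- p + ggplot2::annotate(
      "rect", xmin = light$start_s, xmax = light$end_s,
      ymin = -Inf, ymax = Inf, fill = "gold", alpha = 0.2
    )
  }
  p +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_distance_mm - .data$sem,
                                      ymax = .data$mean_distance_mm + .data$sem),
                         alpha = 0.3, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "mean distance per bin (mm)",
                  colour = "group", fill = "group") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential expression table
#'
#' @param object A `swim_de` tibble from [differential_expression()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot swim_de
#' @export
autoplot.swim_de <- function(object, ...) {
  alpha <- attr(object, "alpha") %||% 0.05
  fc_min <- attr(object, "fc_min") %||% 1
  d <- dplyr::filter(object, .data$tested)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2fc,
                                  y = -log10(.data$p_adj),
                                  colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-fc_min, fc_min), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(up = "firebrick", down = "steelblue",
                                            ns = "grey60")) +
    ggplot2::labs(x = "log2 fold change (treated - control)",
                  y = "-log10 adjusted p") +
    ggplot2::theme_minimal()
}

#' Colour-coded swim path of one larva
#'
#' Draws the trajectory with segments coloured by movement phase
#' (stationary / normal / abrupt), the conventional per-well debug view.
#'
#' @param traj A single-well trajectory tibble.
#' @param thresholds An [activity_thresholds()].
#' @return A ggplot object.
#' @export
plot_trajectory <- function(traj, thresholds = activity_thresholds()) {
  vel <- classify_activity(compute_velocity(traj), thresholds)
  seg <- tibble::tibble(
    x = traj$x_mm[-nrow(traj)], y = traj$y_mm[-nrow(traj)],
    xend = traj$x_mm[-1], yend = traj$y_mm[-1],
    phase = factor(vel$phase, levels = c("stationary", "normal", "abrupt"))
  )
  ggplot2::ggplot(seg, ggplot2::aes(x = .data$x, y = .data$y,
                                    xend = .data$xend, yend = .data$yend,
                                    colour = .data$phase)) +
    ggplot2::geom_segment(linewidth = 0.4) +
    ggplot2::scale_colour_manual(values = c(stationary = "grey70",
                                            normal = "forestgreen",
                                            abrupt = "firebrick"),
                                 drop = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = unique(traj$well)[1]) +
    ggplot2::theme_minimal()
}
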