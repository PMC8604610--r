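# ggplot2 graphics for the main result types.

#' Plot per-paw distance-versus-time traces
#'
#' The classic trackway plot: each paw's x position against time; horizontal
#' runs are contact phases, jumps are swings.
#'
#' @param classified Tibble from [classify_paws()] (or a traces tibble from
#'   [footfall_traces()]).
#' @param fps Frame rate, used if `classified` still has `frame_index`.
#' @return A ggplot object.
#' @export
plot_footfall_traces <- function(classified, fps = 60) {
  tr <- if ("time_s" %in% names(classified)) classified
        else footfall_traces(classified, fps = fps)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$time_s, y = .data$x,
                                   colour = .data$label)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (s)", y = "distance along trackway (px)",
                  colour = "paw") +
    ggplot2::theme_minimal()
}

#' @rdname plot_footfall_traces
#' @param object A `gait_summary` (plots its step table) — traces carry more
#'   information, so prefer [plot_footfall_traces()] on the classified
#'   tibble when available.
#' @param ... Unused.
#' @export
autoplot.gait_summary <- function(object, ...) {
  st <- object$steps
  ggplot2::ggplot(st, ggplot2::aes(x = .data$t_m / object$fps, y = .data$x_m,
                                   colour = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time of step mean frame (s)",
                  y = "step position (px)", colour = "paw") +
    ggplot2::theme_minimal()
}

#' Plot an ROC sweep
#'
#' The empirical ROC polyline with the chance diagonal and the optimal
#' threshold highlighted.
#'
#' @param object A `mousegait_roc` tibble from [roc_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mousegait_roc <- function(object, ...) {
  ot <- optimal_threshold(object)
  pts <- tibble::as_tibble(unclass(object))
  pts <- pts[order(pts$FPR, pts$TPR), ]
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$FPR, y = .data$TPR)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = ot, colour = "red", size = 3) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(title = sprintf("ROC: %s (AUC = %.3f, OT = %g)",
                                  attr(object, "vary") %||% "threshold",
                                  roc_auc(object), ot$threshold)) +
    ggplot2::theme_minimal()
}

#' Group means with confidence intervals
#'
#' A plain mean +/- 95% CI dot plot for comparing a gait parameter across
#' treatment groups. Purely descriptive; no hypothesis testing.
#'
#' @param data A data frame.
#' @param value Column with the parameter values (tidy-eval).
#' @param group Grouping column (tidy-eval).
#' @return A ggplot object.
#' @export
plot_group_means <- function(data, value, group) {
  summ <- data |>
    dplyr::group_by({{ group }}) |>
    dplyr::summarise(mean = mean({{ value }}, na.rm = TRUE),
                     se = stats::sd({{ value }}, na.rm = TRUE) /
                       sqrt(sum(!is.na({{ value }}))),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = {{ group }}, y = .data$mean)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - 1.96 * .data$se,
                                        ymax = .data$mean + 1.96 * .data$se),
                           width = 0.15) +
    ggplot2::labs(y = "mean (95% CI)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
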