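#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a slice-wise fat-fraction profile
#'
#' Mean fat fraction per slice against signed lateral distance to the
#' Y-slice (positive lateral); excluded slices (area at or below the
#' filter) are drawn hollow.
#'
#' @param object A [slice_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.slice_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$distance_mm, y = .data$mean_ff)) +
    ggplot2::geom_line(data = object[object$included, ],
                       colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$included),
                        colour = "steelblue") +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                name = "area > filter") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "lateral distance to Y-slice [mm]",
                  y = "mean fat fraction [%]",
                  title = paste0(object$muscle[1],
                                 if (!is.na(object$case_id[1]))
                                   paste0(" (", object$case_id[1], ")"))) +
    ggplot2::theme_minimal()
}

#' Plot a cohort fat-fraction profile (mean and SD band per muscle)
#'
#' @param object A [aggregate_cohort()] result.
#' @param ... Unused.
#' @return A ggplot faceted by muscle.
#' @export
autoplot.cohort_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$distance_mm, y = .data$mean_ff)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_ff - .data$sd_ff,
                                      ymax = .data$mean_ff + .data$sd_ff),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~muscle) +
    ggplot2::labs(x = "lateral distance to Y-slice [mm]",
                  y = "fat fraction [%] (mean ± SD)") +
    ggplot2::theme_minimal()
}

#' Plot slice-wise prediction error stratified by ground-truth fat class
#'
#' @param object A [per_class_error()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.per_class_error <- function(object, ...) {
  obj <- object[object$n_slices > 0, ]
  ggplot2::ggplot(obj, ggplot2::aes(x = factor(.data$class),
                                    y = .data$mean_error)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_error - .data$sd_error,
      ymax = .data$mean_error + .data$sd_error), colour = "steelblue") +
    ggplot2::labs(x = "ground-truth fat class",
                  y = "slice-wise FF error [%] (mean ± SD)") +
    ggplot2::theme_minimal()
}

#' Plot per-muscle error summaries
#'
#' @param object An [error_summary()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ff_error_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$muscle,
                                       y = .data$mean_error)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_error - .data$sd_error,
      ymax = .data$mean_error + .data$sd_error), colour = "steelblue") +
    ggplot2::labs(x = NULL, y = "signed FF error [%] (mean ± SD)") +
    ggplot2::theme_minimal()
}
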