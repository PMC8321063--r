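# ggplot2 views of the package's result objects.

#' @export
autoplot.slice_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  mid <- attr(object, "mid_height_y")
  ggplot2::ggplot(dplyr::filter(df, .data$ok),
                  ggplot2::aes(x = .data$y_center, y = .data$perimeter)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = mid, linetype = "dashed") +
    ggplot2::labs(x = "height y (cm)", y = "slice perimeter (cm)",
                  title = "Slice circumference profile",
                  subtitle = "dashed line: mid-height") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.body_measurement <- function(object, ...) {
  msr <- object$measurements
  autoplot(object$profile) +
    ggplot2::geom_point(
      data = tibble::tibble(
        y_center = c(msr$hip_y, msr$waist_y),
        perimeter = c(msr$hip_perimeter, msr$waist_perimeter),
        what = c("hip", "waist")),
      ggplot2::aes(colour = .data$what), size = 3) +
    ggplot2::labs(colour = NULL)
}

#' @export
autoplot.icp_registration <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$iteration, y = .data$rmse)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "ICP iteration", y = "correspondence RMSE (cm)",
                  title = "ICP convergence") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.calibration_fit <- function(object, ...) {
  g <- glance(object)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$reference, y = .data$estimate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         linetype = "dotted", colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = g$slope, intercept = g$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = "reference (cm)", y = "estimate (cm)",
                  title = sprintf("Calibration: slope %.3f, r² %.3f",
                                  g$slope, g$r_squared)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sequence_consistency <- function(object, ...) {
  ggplot2::ggplot(object$per_frame,
                  ggplot2::aes(x = .data$frame, y = .data$jaccard)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(x = "frame", y = "Jaccard index",
                  title = "Per-frame segmentation consistency") +
    ggplot2::theme_minimal()
}
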