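# broom-style tidy()/glance() methods for the package's result objects.

#' @export
tidy.sequence_consistency <- function(x, ...) {
  x$per_frame
}

#' @export
glance.sequence_consistency <- function(x, ...) {
  tibble::tibble(
    n_frames = length(x$per_frame_jaccard),
    min_jaccard = x$min_jaccard,
    frac_below_threshold = x$frac_below_threshold,
    threshold = x$threshold,
    max_fn = x$max_fn
  )
}

#' @export
tidy.ellipse_fit <- function(x, ...) {
  tibble::tibble(
    term = c("center_x", "center_y", "a", "b", "angle"),
    estimate = c(x$center[1], x$center[2], x$a, x$b, x$angle)
  )
}

#' @export
glance.ellipse_fit <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, angle = x$angle,
                 center_x = x$center[1], center_y = x$center[2],
                 fit_residual = x$fit_residual, n_points = x$n_points)
}

#' @export
tidy.icp_registration <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$rmse_history), rmse = x$rmse_history)
}

#' @export
glance.icp_registration <- function(x, ...) {
  x$report
}

#' @export
tidy.calibration_fit <- function(x, ...) {
  cf <- coef(x$fit)
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = as.numeric(cf))
}

#' @export
glance.calibration_fit <- function(x, ...) {
  cf <- coef(x$fit)
  tibble::tibble(slope = as.numeric(cf[2]), intercept = as.numeric(cf[1]),
                 r_squared = summary(x$fit)$r.squared, n = x$n)
}

#' @export
augment.calibration_fit <- function(x, ...) {
  dplyr::mutate(x$data, fitted = stats::fitted(x$fit),
                residual = stats::residuals(x$fit))
}

#' @export
tidy.body_measurement <- function(x, ...) {
  tibble::as_tibble(x$profile)
}

#' @export
glance.body_measurement <- function(x, ...) {
  x$measurements
}
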