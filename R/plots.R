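#' @importFrom ggplot2 autoplot
NULL

#' Plot a parameter map
#'
#' Heat map of the valid voxels of a T1 or T2 map, in ms.
#'
#' @param object A [parameter_map()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.samba_parameter_map <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df[df$valid, ],
                  ggplot2::aes(x = .data$x, y = .data$y,
                               fill = .data$value_ms)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = paste0(object$param_name, " (ms)")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste(object$param_name, "map",
                                if (!is.na(object$method)) object$method),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a spiral trajectory
#'
#' k-space locations of every interleaf, colored by arm.
#'
#' @param object A [design_spiral()] trajectory.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.samba_spiral_trajectory <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$kx, y = .data$ky,
                                   color = factor(.data$interleaf))) +
    ggplot2::geom_path(linewidth = 0.3) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "kx (cycles/mm)", y = "ky (cycles/mm)",
                  color = "interleaf") +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot
#'
#' Differences against means with the bias and 95% limits of agreement.
#'
#' @param object A [bland_altman()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.samba_bland_altman <- function(object, ...) {
  df <- tibble::tibble(mean = object$means, diff = object$diffs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$bias, color = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", color = "firebrick") +
    ggplot2::labs(x = "mean of methods (ms)", y = "difference (ms)") +
    ggplot2::theme_minimal()
}

#' Method agreement scatter for an experiment
#'
#' Per-tube means of one method against another (or against ground truth)
#' with the identity line, mirroring a method-comparison regression figure.
#'
#' @param result A [run_experiment()] result.
#' @param param `"T1"` or `"T2"`.
#' @param method_x,method_y Method tags present in the result (or
#'   `"truth"`).
#' @return A ggplot object.
#' @export
plot_method_agreement <- function(result, param = "T1",
                                  method_x = "truth",
                                  method_y = "SA-MBA") {
  stopifnot(inherits(result, "samba_experiment"))
  wide <- result$comparisons[[param]]$per_tube
  ggplot2::ggplot(wide, ggplot2::aes(x = .data[[method_x]],
                                     y = .data[[method_y]])) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = paste(method_x, "(ms)"), y = paste(method_y, "(ms)"),
                  title = paste(param, "agreement")) +
    ggplot2::theme_minimal()
}

#' Repeatability bars for an experiment
#'
#' Per-tube CV% (and optionally the scan-time-normalized product) by
#' method.
#'
#' @param result A [run_experiment()] result.
#' @param param `"T1"` or `"T2"`.
#' @param normalized Plot CV% x scan time (percent-hours) instead of CV%.
#' @return A ggplot object.
#' @export
plot_repeatability <- function(result, param = "T1", normalized = FALSE) {
  stopifnot(inherits(result, "samba_experiment"))
  df <- result$cv[result$cv$param == param, ]
  yvar <- if (normalized) "cv_times_time" else "cv_percent"
  ylab <- if (normalized) "CV% x scan time (%.h)" else "CV%"
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$label),
                                   y = .data[[yvar]],
                                   fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "tube", y = ylab, title = paste(param,
                                                      "repeatability")) +
    ggplot2::theme_minimal()
}
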