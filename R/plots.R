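#' @rdname fit_calibration
#' @export
autoplot.calib_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$level_ug_per_ml, y = .data$response)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "concentration (µg/mL)", y = "response",
      title = if (!is.na(object$analyte)) {
        sprintf("Calibration: %s", object$analyte)
      } else "Calibration",
      subtitle = sprintf("slope %.4g, r = %.5f%s", object$slope, object$r,
                         if (object$zero_forced) ", forced through zero" else "")
    ) +
    ggplot2::theme_minimal()
}

#' RRF versus degree of polymerisation
#'
#' Plots the relative response factor against dp on a log scale, one line
#' per lab if several are present; the steep decay with chain length is the
#' reason each dp class needs its own response factor.
#'
#' @param rrf_table A tibble with columns `analyte`, `rrf` and optionally
#'   `lab` (e.g. [rrf_reference()] or [compute_rrf_table()] output).
#' @return A ggplot object.
#' @export
plot_rrf_profile <- function(rrf_table) {
  check_columns(rrf_table, c("analyte", "rrf"), "RRF table")
  d <- rrf_table |>
    dplyr::filter(is_oligomer(.data$analyte)) |>
    dplyr::mutate(dp = as.integer(sub("^dp", "", .data$analyte)))
  p <- if ("lab" %in% names(d)) {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$dp, y = .data$rrf,
                                    colour = .data$lab))
  } else {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$dp, y = .data$rrf))
  }
  p +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_x_continuous(breaks = 2:10) +
    ggplot2::labs(x = "degree of polymerisation",
                  y = "RRF vs epicatechin (log scale)",
                  title = "Relative response factor by oligomer size") +
    ggplot2::theme_minimal()
}

#' Stability time courses with acceptance bands
#'
#' Plots each analyte's content over time with a shaded band of the
#' acceptance half-width around the timepoint mean.
#'
#' @param data Stability table (`analyte`, `timepoint_h`, `value`, `ip`).
#' @param ip Passed to [stability_assess()] when `data` has no `ip` column.
#' @return A ggplot object.
#' @export
plot_stability <- function(data, ip = NULL) {
  verdict <- stability_assess(data, ip = ip)
  d <- dplyr::left_join(
    dplyr::select(data, "analyte", "timepoint_h", "value"),
    dplyr::select(verdict, "analyte", "mean_value", "acceptable_halfwidth"),
    by = "analyte"
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$timepoint_h, y = .data$value)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_value - .data$acceptable_halfwidth,
                   ymax = .data$mean_value + .data$acceptable_halfwidth),
      fill = "grey85"
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$analyte), scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "content (mg/g)",
                  title = "Extract stability",
                  subtitle = "band: timepoint mean ± acceptance half-width") +
    ggplot2::theme_minimal()
}

#' Z-score chart
#'
#' Per-lab z-scores with the satisfactory (|z| = 2) and unsatisfactory
#' (|z| = 3) limits.
#'
#' @param data Output of [z_scores()]; an `analyte` column, if present,
#'   colours the points.
#' @return A ggplot object.
#' @export
plot_z_scores <- function(data) {
  check_columns(data, c("lab", "z"), "z-score table")
  p <- if ("analyte" %in% names(data)) {
    ggplot2::ggplot(data, ggplot2::aes(x = factor(.data$lab), y = .data$z,
                                       colour = .data$analyte))
  } else {
    ggplot2::ggplot(data, ggplot2::aes(x = factor(.data$lab), y = .data$z))
  }
  p +
    ggplot2::geom_hline(yintercept = c(-3, 3), linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::geom_hline(yintercept = c(-2, 2), linetype = "dotted") +
    ggplot2::geom_point(position = ggplot2::position_jitter(width = 0.1,
                                                            height = 0)) +
    ggplot2::labs(x = "laboratory", y = "z-score",
                  title = "Inter-laboratory z-scores") +
    ggplot2::theme_minimal()
}
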