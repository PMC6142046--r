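# ggplot2 displays for the package's result types.

#' Plot a cell trajectory
#'
#' Protrusion count and longest-protrusion length against time, one panel
#' each.
#'
#' @param object A `cell_trajectory` from [run_simulation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cell_trajectory <- function(object, ...) {
  df <- tibble::as_tibble(object)
  long <- dplyr::bind_rows(
    tibble::tibble(t_min = df$t_min, value = df$llp_um,
                   feature = "longest protrusion (µm)"),
    tibble::tibble(t_min = df$t_min, value = as.numeric(df$n_protrusions),
                   feature = "protrusion count")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_min, y = .data$value)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~feature, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (min)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a calibration history
#'
#' Metric scatter of every evaluated parametrization with the Pareto front
#' highlighted.
#'
#' @param object A `calibration_history` from [run_calibration()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.calibration_history <- function(object, ...) {
  h <- object$history
  ggplot2::ggplot(h, ggplot2::aes(x = .data$BC_llp, y = .data$BC_np)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$pareto), size = 2) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "indianred3", `TRUE` = "dodgerblue3"),
      labels = c(`FALSE` = "evaluated", `TRUE` = "Pareto optimal"),
      name = NULL) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "BC (longest-protrusion length)",
                  y = "BC (protrusion count)") +
    ggplot2::theme_minimal()
}

#' Plot a feature histogram
#'
#' @param hist A [make_histogram()] object.
#' @return A ggplot object.
#' @export
plot_histogram <- function(hist) {
  mid <- (head(hist$edges, -1) + tail(hist$edges, -1)) / 2
  df <- tibble::tibble(mid = mid, freq = hist$freq)
  xlab <- if (hist$feature == "llp") {
    "longest-protrusion length (µm)"
  } else {
    "protrusion count"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$freq)) +
    ggplot2::geom_col(width = diff(hist$edges)[1] * 0.92,
                      fill = "steelblue") +
    ggplot2::labs(x = xlab, y = "probability") +
    ggplot2::theme_minimal()
}

#' Plot a validation sweep
#'
#' Mean velocity along the gradient per condition, with one panel per sweep.
#'
#' @param sweep Tibble from [validation_sweep()].
#' @return A ggplot object.
#' @export
plot_validation_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = factor(.data$value),
                                      y = .data$mean_vx)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_vx - .data$sd_vx / sqrt(.data$n_obs),
      ymax = .data$mean_vx + .data$sd_vx / sqrt(.data$n_obs)), width = 0.2) +
    ggplot2::facet_wrap(~sweep, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "mean v_x (µm/min)") +
    ggplot2::theme_minimal()
}
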