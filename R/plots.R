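#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot traces
#'
#' @param traces trace tibble.
#' @return a ggplot: signal vs time, colored by trace group, faceted by
#'   phase.
#' @export
plot_traces <- function(traces) {
  traces <- validate_traces(traces)
  traces$trace <- interaction(
    format(traces$conc_M * 1e9, digits = 3), traces$replicate_id,
    ifelse(is.na(traces$scavenger), "", traces$scavenger),
    sep = " / ", drop = TRUE
  )
  ggplot2::ggplot(traces, ggplot2::aes(
    .data$time_s, .data$signal,
    color = .data$trace
  )) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~phase, scales = "free") +
    ggplot2::labs(x = "time (s)", y = "normalized signal", color = NULL) +
    ggplot2::theme_minimal()
}

fit_overlay_plot <- function(data, fitted_by_group) {
  grps <- split_traces(data)
  pieces <- purrr::map2(grps, fitted_by_group, function(g, f) {
    g$fitted <- f
    g
  })
  df <- dplyr::bind_rows(pieces, .id = "trace")
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, group = .data$trace)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$signal),
      size = 0.3, alpha = 0.4, color = "grey40"
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), color = "#d55e00") +
    ggplot2::labs(x = "time (s)", y = "normalized signal") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.exp_fit <- function(object, ...) {
  fit_overlay_plot(object$data, list(object$fitted)) +
    ggplot2::ggtitle(sprintf("mono-exponential fit: k = %.3g s^-1", object$k))
}

#' @exportS3Method ggplot2::autoplot
autoplot.biexp_fit <- function(object, ...) {
  fit_overlay_plot(object$data, object$fitted) +
    ggplot2::ggtitle(sprintf(
      "bi-exponential fit: k_fast = %.3g, k_slow = %.3g s^-1",
      object$k_fast, object$k_slow
    ))
}

#' @exportS3Method ggplot2::autoplot
autoplot.dissoc_fit <- function(object, ...) {
  fit_overlay_plot(object$data, object$fitted) +
    ggplot2::ggtitle(sprintf("global dissociation fit: k_off = %.3g s^-1", object$k_off))
}

#' @exportS3Method ggplot2::autoplot
autoplot.assoc_fit <- function(object, ...) {
  fit_overlay_plot(object$data, object$fitted) +
    ggplot2::ggtitle(sprintf("global association fit: k_on = %.3g M^-1 s^-1", object$k_on))
}

#' @exportS3Method ggplot2::autoplot
autoplot.titration_fit <- function(object, ...) {
  lt <- object$data$lt_M
  grid <- 10^seq(log10(min(lt[lt > 0])), log10(max(lt)), length.out = 200)
  curve <- tibble::tibble(
    lt_M = grid,
    response = titration_model(grid, object$rt, object$kd, object$A, object$y0)
  )
  ggplot2::ggplot(object$data, ggplot2::aes(.data$lt_M, .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, color = "#d55e00") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "titrant concentration (M)", y = "normalized response",
      title = if (object$bound_only) {
        sprintf("solution titration: KD < %.3g pM", object$bound * 1e12)
      } else {
        sprintf("solution titration: KD = %.3g pM", object$kd * 1e12)
      }
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.stabilization_panel <- function(object, ...) {
  panel <- object$panel
  panel$k_plot <- dplyr::coalesce(panel$k_mono, object$detection_limit / 10)
  panel$scavenger <- factor(panel$scavenger, levels = rev(panel$scavenger))
  ggplot2::ggplot(panel, ggplot2::aes(
    .data$k_plot, .data$scavenger,
    fill = .data$class
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(
      xintercept = c(object$detection_limit, object$k_free),
      linetype = c("dotted", "dashed")
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "monomerization rate (s^-1), below-detection shown at axis floor",
      y = NULL, fill = "class",
      title = "trimer stabilization panel"
    ) +
    ggplot2::theme_minimal()
}
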