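#' Plot estimated joint angles against the reference
#'
#' @param object an `mhe_fit`.
#' @param ref optional `ref_dataset` overlaid in black.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.mhe_fit <- function(object, ref = NULL, ...) {
  est <- dplyr::filter(tidy(object), .data$kind == "angle") |>
    dplyr::mutate(value = .data$value * 180 / pi)
  p <- ggplot(est, aes(x = .data$time, y = .data$value)) +
    facet_wrap(~channel, scales = "free_y") +
    labs(x = "time (s)", y = "joint angle (deg)")
  if (!is.null(ref)) {
    rf <- dplyr::filter(tidy(ref), .data$kind == "angle") |>
      dplyr::mutate(value = .data$value * 180 / pi)
    p <- p + geom_line(data = rf, colour = "black", linewidth = 0.7)
  }
  p + geom_line(colour = "#d95f02", linewidth = 0.4)
}

#' Plot estimated muscle forces against the reference
#'
#' @param fit an `mhe_fit`.
#' @param ref optional `ref_dataset`.
#' @param muscles optional subset of muscle names.
#' @return A ggplot.
#' @export
plot_forces <- function(fit, ref = NULL, muscles = NULL) {
  est <- dplyr::filter(tidy(fit), .data$kind == "force")
  if (!is.null(muscles)) est <- dplyr::filter(est, .data$channel %in% muscles)
  p <- ggplot(est, aes(x = .data$time, y = .data$value)) +
    facet_wrap(~channel, scales = "free_y") +
    labs(x = "time (s)", y = "muscle force (N)")
  if (!is.null(ref)) {
    rf <- dplyr::filter(tidy(ref), .data$kind == "force")
    if (!is.null(muscles)) rf <- dplyr::filter(rf, .data$channel %in% muscles)
    p <- p + geom_line(data = rf, colour = "black", linewidth = 0.7)
  }
  p + geom_line(colour = "#1b9e77", linewidth = 0.4)
}

#' Plot a window-size sweep (log RMSE vs window size)
#'
#' @param object a `window_sweep` tibble.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.window_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::filter(object, is.finite(.data$window)),
    dplyr::all_of(c("rmse_q_deg", "rmse_force_n", "rmse_markers_m")),
    names_to = "quantity", values_to = "rmse")
  ggplot(long, aes(x = .data$window, y = .data$rmse,
                   colour = .data$formulation)) +
    geom_line() + geom_point() +
    facet_wrap(~quantity, scales = "free_y") +
    scale_y_log10() +
    labs(x = "window size (frames)", y = "RMSE (log scale)")
}

#' Boxplots of grid RMSE by noise and co-contraction factors
#'
#' @param object a `score_table`.
#' @param response RMSE column to plot.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.score_table <- function(object, response = "rmse_force_n", ...) {
  ggplot(dplyr::filter(object, .data$kept %in% TRUE),
         aes(x = .data$cocontraction, y = .data[[response]],
             fill = .data$emg_noise)) +
    geom_boxplot() +
    facet_wrap(~variant) +
    labs(x = "co-contraction level", y = response, fill = "EMG noise")
}
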