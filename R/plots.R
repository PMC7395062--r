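# Optional ggplot2 graphics (ggplot2 is suggested, not imported).

#' Plot a dose-response curve with its Hill fit
#'
#' @param conc Molar concentrations (> 0).
#' @param response Responses (percent).
#' @param fit Optional `hill_fit` overlaid as a line.
#' @param ylab Axis label.
#' @return A ggplot object.
#' @export
plot_dose_response <- function(conc, response, fit = NULL, ylab = "response (%)") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_domain("ggplot2 is required for plotting")
  }
  df <- tibble::tibble(x = log10(conc), y = response)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "log10 concentration (M)", y = ylab) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    grid <- seq(min(df$x), max(df$x), length.out = 200)
    line <- tibble::tibble(x = grid, y = predict_hill4(fit, 10^grid))
    p <- p + ggplot2::geom_line(data = line)
  }
  p
}

#' Scatter plot of two endpoints with the OLS line
#'
#' @param x,y Response tibbles as for [correlate_endpoints()].
#' @param endpoint_x,endpoint_y Axis labels.
#' @return A ggplot object.
#' @export
plot_endpoint_correlation <- function(x, y, endpoint_x = "x", endpoint_y = "y") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_domain("ggplot2 is required for plotting")
  }
  merged <- dplyr::inner_join(x, y, by = c("compound", "conc_M"), suffix = c("_x", "_y"))
  stats <- correlate_endpoints(x, y, endpoint_x, endpoint_y)
  ggplot2::ggplot(merged, ggplot2::aes(x = .data$response_x, y = .data$response_y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = stats$slope, intercept = stats$intercept) +
    ggplot2::labs(
      x = endpoint_x, y = endpoint_y,
      subtitle = sprintf("slope %.2f, r² = %.3f (n = %d)", stats$slope, stats$r2, stats$n)
    ) +
    ggplot2::theme_minimal()
}
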