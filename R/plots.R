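#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_rect
#'   geom_abline labs theme_minimal annotate
#' @export
ggplot2::autoplot

#' Plot a pore trace
#'
#' Pore radius (um) versus time (ms), raw measurements as filled points and
#' the moving-average smoothed series as open circles.
#'
#' @param object A `guv_pore_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot guv_pore_trace
#' @export
autoplot.guv_pore_trace <- function(object, ...) {
  df <- dplyr::filter(object, .data$valid)
  ggplot(df, aes(x = .data$time_ms)) +
    geom_point(aes(y = .data$radius_um, colour = "raw"), size = 1.6) +
    geom_point(aes(y = .data$smoothed, colour = "smoothed"),
               shape = 1, size = 2.2) +
    ggplot2::scale_colour_manual(
      values = c(raw = "#c2185b", smoothed = "#1e66a8"), name = NULL) +
    labs(x = "time (ms)", y = "pore radius (µm)") +
    theme_minimal()
}

#' Plot the pore dynamics and edge-tension fit
#'
#' The transformed ordinate R^2 ln r (um^2) versus time (ms): raw values as
#' filled points, values from the smoothed radii as open circles, the
#' selected linear slow-closure region shaded, and the fitted line whose
#' slope gives the edge tension.
#'
#' @param object A `guv_edge_tension` (ideally from [pore_analyze()], so the
#'   smoothed series is available).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot guv_edge_tension
#' @export
autoplot.guv_edge_tension <- function(object, ...) {
  df <- object$data
  df$t_raw <- df$t
  if (!is.null(object$trace) && !is.null(object$geometry)) {
    tr <- object$trace
    open <- tr$is_open & tr$valid & tr$radius_um > 0
    df$y_smooth <- object$geometry$radius_after^2 * log(tr$smoothed[open])
  } else {
    df$y_smooth <- NA_real_
  }
  reg <- df[df$in_region, ]
  p <- ggplot(df, aes(x = .data$t)) +
    geom_point(aes(y = .data$y, colour = "raw"), size = 1.6)
  if (any(is.finite(df$y_smooth))) {
    p <- p + geom_point(aes(y = .data$y_smooth, colour = "smoothed"),
                        shape = 1, size = 2.2)
  }
  p +
    annotate("rect", xmin = min(reg$t), xmax = max(reg$t),
             ymin = -Inf, ymax = Inf, alpha = 0.12, fill = "#7fb3d5") +
    geom_abline(slope = object$slope, intercept = object$intercept,
                colour = "red", linewidth = 0.7) +
    ggplot2::scale_colour_manual(
      values = c(raw = "#c2185b", smoothed = "#1e66a8"), name = NULL) +
    labs(
      x = "time (ms)",
      y = expression(R^2 * ln * italic(r) ~ (mu * m^2)),
      title = sprintf("edge tension %.1f pN (slope %.3g µm²/ms, R² = %.3f)",
                      object$gamma_pN, object$slope, object$r_squared)
    ) +
    theme_minimal()
}

#' @importFrom rlang .data
NULL
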