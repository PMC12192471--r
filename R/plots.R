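#' Plot an NPS curve
#'
#' Line plot of noise power (or relative improvement, with a reference line
#' at zero) against spatial frequency; sparsely supported bins beyond the
#' axis Nyquist frequency are drawn with reduced alpha.
#'
#' @param object A `nps_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nps_curve <- function(object, ...) {
  full <- max(object$support_count)
  df <- as_tibble(object)
  df$full_support <- df$support_count == full
  ylab <- if (curve_kind(object) == "relative") {
    "relative improvement (%)"
  } else {
    expression(NPS ~ (HU^2 ~ mm^2))
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency, y = .data$power,
                                        alpha = .data$full_support)) +
    ggplot2::geom_line(ggplot2::aes(group = 1)) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35),
                                guide = "none") +
    ggplot2::labs(x = "spatial frequency (1/mm)", y = ylab) +
    ggplot2::theme_minimal()
  if (curve_kind(object) == "relative") {
    p <- p + ggplot2::geom_hline(yintercept = 0, colour = "red",
                                 linewidth = 0.3)
  }
  p
}

#' Compare the NPS curves of several runs
#'
#' @param curves Named list of `nps_curve`s (names become the legend).
#' @return A ggplot object.
#' @export
plot_nps_comparison <- function(curves) {
  df <- purrr::imap_dfr(curves, function(cv, nm) {
    tibble(run = nm, frequency = cv$frequency, power = cv$power)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency, y = .data$power,
                                   colour = .data$run)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "spatial frequency (1/mm)",
                  y = expression(NPS ~ (HU^2 ~ mm^2)), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Heat-map of a 2-d power map
#'
#' @param map A `power_map`.
#' @param trans Transformation for the fill scale (default `"sqrt"`).
#' @return A ggplot object.
#' @export
plot_power_map <- function(map, trans = "sqrt") {
  stopifnot(inherits(map, "power_map"))
  df <- expand.grid(fx = map$fx, fy = map$fy)
  df$power <- as.vector(map$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fx, y = .data$fy,
                                   fill = .data$power)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(trans = trans) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "fx (1/mm)", y = "fy (1/mm)",
                  fill = expression(HU^2 ~ mm^2)) +
    ggplot2::theme_minimal()
}
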