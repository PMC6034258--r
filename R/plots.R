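#' Plot a force curve
#'
#' Force (or raw deflection) versus Z displacement.
#'
#' @param object An `fv_curve`.
#' @param ... Unused.
#' @returns A ggplot.
#' @export
autoplot.fv_curve <- function(object, ...) {
  ycol <- if ("force" %in% names(object)) "force" else "deflection"
  ylab <- if (ycol == "force") "force (nN)" else
    sprintf("deflection (%s)", attr(object, "deflection_unit"))
  ggplot2::ggplot(object, ggplot2::aes(x = .data$z, y = .data[[ycol]])) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = if (isTRUE(attr(object, "calibrated"))) "z (nm)" else "z (raw)",
      y = ylab
    ) +
    ggplot2::theme_minimal()
}

#' Contact-point diagnostic plot
#'
#' The processed curve with the identified contact point marked by a
#' vertical line, for visual check-up of the chosen routine.
#'
#' @param curve A processed `fv_curve`.
#' @param cp An `fv_contact_point`.
#' @returns A ggplot.
#' @export
plot_cp_diagnostic <- function(curve, cp) {
  autoplot(curve) +
    ggplot2::geom_vline(xintercept = cp$z_cp, colour = "red") +
    ggplot2::labs(subtitle = sprintf(
      "contact point: z = %.4g nm (%s)", cp$z_cp, cp$method
    ))
}

#' Plot an indentation curve against squared depth
#'
#' In Sneddon-type conical/pyramidal contact, force is linear in
#' \eqn{\delta^2}; departures from a straight line flag contact-point error
#' or depth-dependent stiffness.
#'
#' @param object An `fv_indentation`.
#' @param squared Plot against \eqn{\delta^2} (default) or \eqn{\delta}.
#' @param ... Unused.
#' @returns A ggplot.
#' @export
autoplot.fv_indentation <- function(object, squared = TRUE, ...) {
  df <- tibble::tibble(
    x = if (squared) object$delta^2 else object$delta,
    force = object$force
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$force)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::labs(
      x = if (squared) expression(delta^2 ~ (nm^2)) else expression(delta ~ (nm)),
      y = "force (nN)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a result map
#'
#' One tile per pixel with row `y = 0` at the bottom (maps are spatial,
#' bottom-left origin); darker tiles are lower values.
#'
#' @param object An `fv_map`.
#' @param ... Unused.
#' @returns A ggplot.
#' @export
autoplot.fv_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey50") +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = attr(object, "unit"), title = attr(object, "map_name")) +
    ggplot2::theme_minimal()
}
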