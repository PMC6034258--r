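#' Tidy the fitted objects
#'
#' broom-style one-row-per-term summaries of the package's fit results.
#'
#' @param x An `fv_zeroline`, `fv_stiffness`, `fv_modulus` or
#'   `fv_acquisition` object.
#' @param ... Unused.
#' @returns A tibble.
#' @name fcvolume-tidiers
NULL

#' @rdname fcvolume-tidiers
#' @export
tidy.fv_zeroline <- function(x, ...) {
  tibble::tibble(
    term = c("slope", "intercept"),
    estimate = c(x$slope, x$intercept),
    unit = c("nN/nm", "nN")
  )
}

#' @rdname fcvolume-tidiers
#' @export
glance.fv_zeroline <- function(x, ...) {
  tibble::tibble(
    n = x$n, sigma = x$sigma, se_slope = x$se_slope,
    window_lo = x$window[1], window_hi = x$window[2]
  )
}

#' @rdname fcvolume-tidiers
#' @export
tidy.fv_stiffness <- function(x, ...) {
  tibble::tibble(
    term = c("slope", "slope_raw", "intercept"),
    estimate = c(x$slope, x$slope_raw, x$intercept),
    unit = c("nN/nm", "V/nm", "nN")
  )
}

#' @rdname fcvolume-tidiers
#' @export
glance.fv_stiffness <- function(x, ...) {
  tibble::tibble(
    n = x$n, sigma = x$sigma,
    window_lo = x$window[1], window_hi = x$window[2]
  )
}

#' @rdname fcvolume-tidiers
#' @export
tidy.fv_modulus <- function(x, ...) {
  tibble::tibble(
    term = c("E", "B", "intercept"),
    estimate = c(x$E, x$B, x$intercept),
    unit = c(x$unit, "nN/nm^2", "nN")
  )
}

#' @rdname fcvolume-tidiers
#' @export
glance.fv_modulus <- function(x, ...) {
  tibble::tibble(
    n = x$n, sigma = x$sigma,
    window_lo = x$window[1], window_hi = x$window[2],
    tip_shape = x$tip$shape, alpha_deg = x$tip$alpha_deg,
    c0 = x$tip$c0, nu = x$tip$nu
  )
}

#' @rdname fcvolume-tidiers
#' @export
tidy.fv_acquisition <- function(x, ...) {
  tibble::tibble(
    term = c(
      "z_stage_sensitivity", "cantilever_k", "detector_sensitivity",
      "inverse_sensitivity"
    ),
    estimate = c(
      x$z_stage_sensitivity, x$cantilever_k, x$detector_sensitivity,
      1 / x$detector_sensitivity
    ),
    unit = c("nm/unit", "N/m", "V/nm", "nm/V")
  )
}

#' @export
print.fv_contact_point <- function(x, ...) {
  cat(sprintf(
    "<contact point> index %d, z = %.6g nm (%s)\n", x$index, x$z_cp, x$method
  ))
  invisible(x)
}

#' @export
print.fv_modulus <- function(x, ...) {
  cat(sprintf(
    "<modulus fit> E = %.6g %s (B = %.6g nN/nm^2, window %g-%g%%, n = %d)\n",
    x$E, x$unit, x$B, x$window[1], x$window[2], x$n
  ))
  invisible(x)
}

#' @export
print.fv_stiffness <- function(x, ...) {
  cat(sprintf(
    "<stiffness fit> slope = %.6g nN/nm (window %g-%g%%, n = %d)\n",
    x$slope, x$window[1], x$window[2], x$n
  ))
  invisible(x)
}

#' @export
print.fv_zeroline <- function(x, ...) {
  cat(sprintf(
    "<zeroline fit> slope = %.6g nN/nm, intercept = %.6g nN (window %g-%g%%)\n",
    x$slope, x$intercept, x$window[1], x$window[2]
  ))
  invisible(x)
}
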