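#' Tip contact model
#'
#' Sneddon's solution for a conical indenter, with Bilodeau's geometric
#' correction for a four-sided pyramid, predicts
#' \deqn{F = C_0 \frac{2 E \delta^2}{\pi (1 - \nu^2) \tan\alpha}}
#' so the indentation curve \eqn{F} vs \eqn{\delta^2} is a straight line
#' whose slope carries the Young's modulus.
#'
#' @param shape `"cone"` (`C0 = 1`) or `"pyramid4"` (`C0 = 1.46`).
#' @param alpha_deg Tip opening half-angle \eqn{\alpha}, degrees.
#' @param c0 Optional override of the Bilodeau coefficient.
#' @param nu Poisson ratio \eqn{\nu} (0.5 = incompressible, the usual choice
#'   for soft biological samples).
#' @returns An `fv_tip` list.
#' @export
fv_tip <- function(shape = c("pyramid4", "cone"), alpha_deg = 23.5,
                   c0 = NULL, nu = 0.5) {
  shape <- match.arg(shape)
  c0 <- c0 %||% switch(shape, cone = 1, pyramid4 = 1.46)
  if (!(alpha_deg > 0 && alpha_deg < 90)) {
    abort("alpha_deg must be in (0, 90)", class = "fcv_param_error")
  }
  if (c0 <= 0) abort("c0 must be > 0", class = "fcv_param_error")
  if (!(nu >= 0 && nu <= 0.5)) {
    abort("nu must be in [0, 0.5]", class = "fcv_param_error")
  }
  structure(list(shape = shape, alpha_deg = alpha_deg, c0 = c0, nu = nu),
    class = "fv_tip"
  )
}

# stiffness (slope of F vs delta^2) predicted by the tip model, nN/nm^2 per GPa
tip_prefactor <- function(tip) {
  2 * tip$c0 / (pi * (1 - tip$nu^2) * tan(tip$alpha_deg * pi / 180))
}

e_unit_factor <- function(unit = c("kPa", "MPa", "GPa")) {
  switch(match.arg(unit), kPa = 1e6, MPa = 1e3, GPa = 1)
}

#' Contact-line stiffness of one pixel
#'
#' Ordinary least-squares slope of force versus z over a window of the
#' contact line, where 0% is the contact point and 100% the point of maximum
#' load.  On undeformable samples this slope saturates at \eqn{K_C}
#' (equivalently `S` in raw V/nm terms); softer pixels give smaller slopes,
#' so the map ranks stiffness without assuming a contact model.
#'
#' @param curve A calibrated, baseline-subtracted approach `fv_curve`.
#' @param cp An `fv_contact_point`.
#' @param window Percentage pair of the contact line (default the full
#'   0--100%).
#' @param params Optional [fv_acquisition()]; when supplied, the slope is
#'   also reported in raw detector units (V/nm) as `slope_raw`.
#' @returns An `fv_stiffness` object with `slope` (nN/nm), `slope_raw`
#'   (V/nm or `NA`), `window`, and fit diagnostics.
#' @export
fit_stiffness <- function(curve, cp, window = c(0, 100), params = NULL) {
  idx_all <- cp$index:nrow(curve)
  idx <- idx_all[window_indices(window, length(idx_all))]
  fit <- ols_line(curve$z[idx], curve$force[idx])
  slope_raw <- if (!is.null(params)) {
    fit$slope * params$detector_sensitivity / params$cantilever_k
  } else {
    NA_real_
  }
  structure(list(
    slope = fit$slope, slope_raw = slope_raw, intercept = fit$intercept,
    window = window, n = fit$n, sigma = fit$sigma
  ), class = "fv_stiffness")
}

#' Young's modulus from an indentation curve
#'
#' The windowed points of the indentation curve are fitted by ordinary least
#' squares as \eqn{F = B \delta^2 + const} (free intercept, absorbing
#' residual contact-point error), and the slope is converted to a modulus by
#' inverting the tip model:
#' \deqn{E = \frac{\pi B (1 - \nu^2) \tan\alpha}{2 C_0}}
#' which for \eqn{\nu = 0.5} reduces to \eqn{E = 3 \pi B \tan\alpha / (8 C_0)}.
#' With \eqn{B} in nN/nm\eqn{^2} the modulus comes out in GPa and is then
#' converted to the requested unit.
#'
#' The window is a *depth* window: percentages of the maximum indentation
#' depth (0% = contact point, 100% = maximum load), so tomography windows
#' select true depth ranges rather than sample counts.
#'
#' @param ind An `fv_indentation`.
#' @param tip An [fv_tip()].
#' @param window Depth-percentage pair, default `c(0, 100)`.
#' @param unit `"kPa"`, `"MPa"` or `"GPa"`.
#' @returns An `fv_modulus` object with `E` (requested unit), `B`
#'   (nN/nm\eqn{^2}), `intercept`, `window`, `unit`, `n`, `sigma`.  Negative
#'   fitted slopes yield a negative `E` with a warning (a diagnostic, not
#'   silently clipped); rigid pixels (all \eqn{\delta} zero) are flagged by
#'   an error of class `fcv_fit_error`.
#' @examples
#' ind <- structure(
#'   tibble::tibble(delta = 0:100, force = 0.001 * (0:100)^2),
#'   class = c("fv_indentation", class(tibble::tibble()))
#' )
#' fit_modulus(ind, fv_tip("pyramid4", 23.5), unit = "kPa")$E # ~351 kPa
#' @export
fit_modulus <- function(ind, tip = fv_tip(), window = c(0, 100),
                        unit = c("kPa", "MPa", "GPa")) {
  unit <- match.arg(unit)
  dmax <- max(ind$delta)
  lo <- window[1] / 100 * dmax
  hi <- window[2] / 100 * dmax
  if (!(window[1] >= 0 && window[2] <= 100 && window[1] < window[2])) {
    abort("window percentages must satisfy 0 <= p0 < p1 <= 100",
      class = "fcv_window_error"
    )
  }
  keep <- ind$delta >= lo & ind$delta <= hi
  if (sum(keep) < 2L) {
    abort(sprintf(
      "fewer than 2 indentation points in the %g-%g%% depth window",
      window[1], window[2]
    ), class = "fcv_fit_error")
  }
  fit <- ols_line(ind$delta[keep]^2, ind$force[keep])
  e_gpa <- pi * fit$slope * (1 - tip$nu^2) * tan(tip$alpha_deg * pi / 180) /
    (2 * tip$c0)
  if (fit$slope < 0) {
    warn("negative indentation-curve slope: reporting a negative modulus")
  }
  structure(list(
    E = e_gpa * e_unit_factor(unit), B = fit$slope, intercept = fit$intercept,
    window = window, unit = unit, n = fit$n, sigma = fit$sigma,
    tip = tip
  ), class = "fv_modulus")
}

#' Depth-resolved modulus fits (force tomography)
#'
#' Fits the same indentation curve over several depth windows (e.g. the
#' 0--35%, 40--75% and 80--100% scheme), resolving stiffness as a function of
#' penetration and revealing stiffer material buried under a softer surface.
#' Per-window failures are collected, not fatal to the other windows.
#'
#' @inheritParams fit_modulus
#' @param windows List of depth-percentage pairs.
#' @returns A named list of `fv_modulus` results (or `condition` objects for
#'   failed windows), keyed `"<p0>_<p1>"` so output file names can carry the
#'   window extremities.
#' @export
tomography <- function(ind, tip = fv_tip(),
                       windows = list(c(0, 35), c(40, 75), c(80, 100)),
                       unit = c("kPa", "MPa", "GPa")) {
  unit <- match.arg(unit)
  names(windows) <- vapply(
    windows, function(w) sprintf("%g_%g", w[1], w[2]), ""
  )
  purrr::map(windows, function(w) {
    tryCatch(fit_modulus(ind, tip, w, unit), error = function(e) e)
  })
}
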