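#' Acquisition parameters
#'
#' Bundles the instrument calibration needed to turn raw curve columns into
#' physical units, plus the map layout used to place progressive files.
#'
#' The deflection signal `D` (volts) becomes a force through
#' \eqn{F = D K_C / S} in nN.  When the deflection column is already a force
#' (`deflection_unit = "N"`, i.e. the file stores nN), `cantilever_k` and
#' `detector_sensitivity` must both be 1 so the column passes through.
#'
#' @param z_stage_sensitivity nm per raw Z unit (1000 for Z stored in um,
#'   the calibrated nm/step for stepper stages, 1 for Z already in nm).
#' @param cantilever_k Cantilever elastic constant \eqn{K_C}, N/m
#'   (numerically nN/nm).
#' @param detector_sensitivity Detector sensitivity \eqn{S}, V/nm, measured
#'   as the approach slope on an incompressible surface.
#' @param deflection_unit `"V"` or `"N"` (nN passthrough).
#' @param curves_per_row,scan_modality,naming_mode Map layout, see
#'   [decode_position()] and [parse_filename()].
#' @param curve_type `"complete"` (approach + withdraw in each file) or
#'   `"approach_only"`.
#' @param z_direction `"increasing"` if stored Z grows as the tip advances
#'   toward the sample (the package's internal convention), `"decreasing"`
#'   for instruments storing the opposite sign; such curves are flipped on
#'   calibration.
#' @returns An `fv_acquisition` list.  `tidy()` on it reports the derived
#'   inverse sensitivity in nm/V alongside the raw parameters.
#' @export
fv_acquisition <- function(z_stage_sensitivity = 1,
                           cantilever_k = 1,
                           detector_sensitivity = 1,
                           deflection_unit = c("V", "N"),
                           curves_per_row = NULL,
                           scan_modality = c("row_x_row", "raster"),
                           naming_mode = c("explicit", "progressive"),
                           curve_type = c("complete", "approach_only"),
                           z_direction = c("increasing", "decreasing")) {
  deflection_unit <- match.arg(deflection_unit)
  if (z_stage_sensitivity <= 0 || cantilever_k <= 0 || detector_sensitivity <= 0) {
    abort("all sensitivities must be > 0", class = "fcv_param_error")
  }
  if (deflection_unit == "N" && (cantilever_k != 1 || detector_sensitivity != 1)) {
    abort("with deflection in N, cantilever_k and detector_sensitivity must both be 1",
      class = "fcv_param_error"
    )
  }
  structure(list(
    z_stage_sensitivity = z_stage_sensitivity,
    cantilever_k = cantilever_k,
    detector_sensitivity = detector_sensitivity,
    deflection_unit = deflection_unit,
    curves_per_row = curves_per_row,
    scan_modality = match.arg(scan_modality),
    naming_mode = match.arg(naming_mode),
    curve_type = match.arg(curve_type),
    z_direction = match.arg(z_direction)
  ), class = "fv_acquisition")
}

#' Keep the approach half of a complete force curve
#'
#' Complete curves store approach then withdraw; the cut follows the
#' Z-displacement axis: samples up to and including the Z extremum (the
#' turnaround, taken at the last sample of any flat apex) are kept.
#'
#' @param curve An `fv_curve`.
#' @param curve_type `"complete"` or `"approach_only"` (identity).
#' @returns The approach-only `fv_curve`.
#' @export
split_approach <- function(curve, curve_type = c("complete", "approach_only")) {
  curve_type <- match.arg(curve_type)
  if (curve_type == "approach_only") {
    return(keep_curve_attrs(curve, curve, direction = "approach"))
  }
  z <- curve$z
  # advance direction: toward the extremum reached first along the stored order
  apex <- if (abs(max(z) - z[1]) >= abs(min(z) - z[1])) max(z) else min(z)
  cut <- max(which(z == apex))
  if (cut == length(z)) {
    warn("no interior Z turnaround found; keeping the whole curve as approach")
  }
  keep_curve_attrs(curve[seq_len(cut), ], curve, direction = "approach")
}

#' Convert a raw curve to physical units
#'
#' Z is scaled to nm by the stage sensitivity; deflection volts become force
#' in nN through \eqn{F = D K_C / S}.  With `deflection_unit = "N"` the
#' deflection column is already nN and passes through unchanged
#' (`K_C = S = 1`).  Curves whose stored Z decreases during approach
#' (`z_direction = "decreasing"`) are sign-flipped so that increasing `z`
#' always means the tip advancing, with the maximum load at the last sample.
#'
#' @param curve An `fv_curve` (raw, from [load_curve()]).
#' @param params An [fv_acquisition()].
#' @returns A calibrated `fv_curve` with columns `z` (nm), `deflection`
#'   (original unit) and `force` (nN).
#' @export
to_physical <- function(curve, params) {
  stopifnot(inherits(params, "fv_acquisition"))
  z <- curve$z * params$z_stage_sensitivity
  if (params$z_direction == "decreasing") z <- -z
  force <- curve$deflection * params$cantilever_k / params$detector_sensitivity
  keep_curve_attrs(
    tibble::tibble(z = z, deflection = curve$deflection, force = force),
    curve,
    calibrated = TRUE
  )
}

#' Fit the zero-force baseline of an approach curve
#'
#' An ordinary least-squares line is fitted to force versus z over a window
#' given as percentages of the curve: 0% is the first sample (farthest from
#' the surface), 100% the point of maximum load.  Fig.-2-style defaults such
#' as 10--70% keep the fit inside the non-contact region.
#'
#' @param curve A calibrated approach `fv_curve`.
#' @param window Percentage pair `c(p0, p1)`.
#' @returns An `fv_zeroline` object with `slope` (nN/nm), `intercept` (nN),
#'   `window`, and fit diagnostics.  Supports [tidy()] and [glance()].
#' @export
fit_zeroline <- function(curve, window = c(0, 70)) {
  idx <- window_indices(window, nrow(curve))
  fit <- ols_line(curve$z[idx], curve$force[idx])
  structure(list(
    slope = fit$slope, intercept = fit$intercept, window = window,
    n = fit$n, sigma = fit$sigma, se_slope = fit$se_slope
  ), class = "fv_zeroline")
}

#' Subtract a fitted zeroline from a curve
#'
#' @param curve A calibrated `fv_curve`.
#' @param fit An [fit_zeroline()] result for this curve.
#' @returns The curve with `force` replaced by the baseline-subtracted force;
#'   the mean residual over the fitted window is zero up to the fit residual.
#' @export
subtract_zeroline <- function(curve, fit) {
  stopifnot(inherits(fit, "fv_zeroline"))
  out <- curve
  out$force <- curve$force - (fit$slope * curve$z + fit$intercept)
  keep_curve_attrs(out, curve, baseline_removed = TRUE)
}
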