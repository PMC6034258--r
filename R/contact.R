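#' Centered moving-average smoothing
#'
#' Window of `n` samples centered on each point, truncated symmetrically at
#' the edges so the output has the input's length and features keep their
#' position.  Even `n` is incremented to the next odd value.
#'
#' @param y Numeric vector.
#' @param n Window width in samples (>= 1).
#' @returns Smoothed vector, same length as `y`.
#' @examples
#' moving_average(c(0, 0, 3, 0, 0), 3) # 0 1 1 1 0
#' @export
moving_average <- function(y, n) {
  n <- as.integer(n)
  if (n < 1L) abort("smoothing window must be >= 1", class = "fcv_param_error")
  N <- length(y)
  if (n > N) {
    abort("smoothing window exceeds the curve length", class = "fcv_param_error")
  }
  if (n %% 2L == 0L) n <- n + 1L
  if (n == 1L) return(y)
  k <- (n - 1L) %/% 2L
  i <- seq_len(N)
  h <- pmin(k, i - 1L, N - i) # symmetric truncation at the edges
  cs <- cumsum(c(0, y))
  (cs[i + h + 1L] - cs[i - h]) / (2L * h + 1L)
}

smooth_halfwidth <- function(n_smooth) {
  n <- as.integer(n_smooth)
  if (n %% 2L == 0L) n <- n + 1L
  (n - 1L) %/% 2L
}

# two-point central difference, one-sided at the ends
finite_derivative <- function(y, x) {
  N <- length(y)
  d <- numeric(N)
  d[1] <- (y[2] - y[1]) / (x[2] - x[1])
  d[N] <- (y[N] - y[N - 1]) / (x[N] - x[N - 1])
  if (N > 2L) {
    i <- 2:(N - 1)
    d[i] <- (y[i + 1] - y[i - 1]) / (x[i + 1] - x[i - 1])
  }
  d
}

#' Contact-point parameters
#'
#' @param n_smooth Moving-average window (samples) for the smoothing-based
#'   routines; even values are used as the next odd number.
#' @param contact_window Percentage pair of the whole curve over which the
#'   contact line is fitted by the `fit_intersection` routine (Fig.-3 style
#'   default 90--100%).
#' @param zero_window Zeroline window reused by `fit_intersection` for the
#'   residual zero-line fit.
#' @returns An `fv_cp_params` list.
#' @export
fv_cp_params <- function(n_smooth = 5L, contact_window = c(90, 100),
                         zero_window = c(0, 70)) {
  if (n_smooth < 1L) abort("n_smooth must be >= 1", class = "fcv_param_error")
  structure(list(
    n_smooth = as.integer(n_smooth),
    contact_window = contact_window, zero_window = zero_window
  ), class = "fv_cp_params")
}

new_contact_point <- function(curve, index, method) {
  structure(list(
    index = as.integer(index), z_cp = curve$z[index], method = method
  ), class = "fv_contact_point")
}

cp_not_found <- function(curve, why) {
  abort(sprintf(
    "contact point not found for curve at grid position (%s, %s): %s",
    attr(curve, "grid_x"), attr(curve, "grid_y"), why
  ), class = "fcv_cp_error")
}

#' Contact point from the smoothed derivative (routine i)
#'
#' The force curve is smoothed (window `n_smooth`), differentiated with
#' respect to z, and the derivative smoothed again with the same window.
#' Scanning from the point of maximum load toward the start, the contact
#' point is the first sample where the smoothed derivative touches zero
#' (|value| below `1e-12` of its maximum magnitude) or changes sign.
#' Effective on noisy curves, at the cost of heavier smoothing.
#'
#' @param curve A baseline-subtracted approach `fv_curve`.
#' @param params An [fv_cp_params()].
#' @returns An `fv_contact_point` with `index`, `z_cp` (nm) and `method`.
#' @export
cp_derivative_smooth <- function(curve, params = fv_cp_params()) {
  stopifnot(isTRUE(attr(curve, "baseline_removed")))
  fs <- moving_average(curve$force, params$n_smooth)
  d <- moving_average(finite_derivative(fs, curve$z), params$n_smooth)
  N <- length(d)
  tol <- 1e-12 * max(abs(d))
  touches <- abs(d) <= tol
  flips <- c(sign(d[-N]) != sign(d[-1]) & sign(d[-N]) != 0 & sign(d[-1]) != 0, FALSE)
  # the scan starts at the last fully smoothed sample: edge windows are
  # truncated, so the trailing samples carry nearly raw noise
  k <- smooth_halfwidth(params$n_smooth)
  hit <- which(touches | flips)
  hit <- hit[hit <= N - k]
  if (length(hit) == 0L) {
    cp_not_found(curve, "smoothed derivative never reaches zero")
  }
  new_contact_point(curve, max(hit), "derivative_smooth")
}

#' Contact point from the smoothed curve minimum (routine ii)
#'
#' The force curve is smoothed and scanned from the point of maximum load
#' toward the start; the contact point is the first local minimum met (a
#' sample not above either neighbour, plateaus resolving to the sample
#' nearest maximum load).  If no interior local minimum exists the global
#' minimum is used with a warning.  Suited to low-noise curves, where the
#' minimum marks the adhesive dip at contact.
#'
#' @inheritParams cp_derivative_smooth
#' @returns An `fv_contact_point`.
#' @export
cp_lowest_value_smooth <- function(curve, params = fv_cp_params()) {
  stopifnot(isTRUE(attr(curve, "baseline_removed")))
  N <- nrow(curve)
  if (N < 3L) abort("curve shorter than 3 samples", class = "fcv_format_error")
  fs <- moving_average(curve$force, params$n_smooth)
  i <- 2:(N - 1)
  local_min <- fs[i] <= fs[i - 1] & fs[i] <= fs[i + 1]
  hit <- which(local_min)
  hit <- hit[hit + 1L <= N - smooth_halfwidth(params$n_smooth)]
  if (length(hit) == 0L) {
    warn("no interior local minimum; falling back to the global minimum")
    idx <- max(which(fs == min(fs)))
  } else {
    idx <- max(hit) + 1L # nearest to maximum load
  }
  new_contact_point(curve, idx, "lowest_value_smooth")
}

#' Contact point from the two-line intersection (routine iii)
#'
#' A contact line is fitted over the upper window of the curve (default
#' 90--100%) and intersected with the residual zero-line fit of the
#' baseline-subtracted curve (slope ~ 0 after subtraction); the contact
#' point is the sample whose z is closest to the intersection.  Suited to
#' hard samples, whose contact region is nearly straight.
#'
#' @inheritParams cp_derivative_smooth
#' @param zeroline Optional [fit_zeroline()] of the *subtracted* curve over
#'   `params$zero_window`; refitted internally when omitted.
#' @returns An `fv_contact_point`.
#' @export
cp_fit_intersection <- function(curve, params = fv_cp_params(), zeroline = NULL) {
  stopifnot(isTRUE(attr(curve, "baseline_removed")))
  if (is.null(zeroline)) {
    zeroline <- fit_zeroline(curve, params$zero_window)
  }
  idx <- window_indices(params$contact_window, nrow(curve))
  contact <- ols_line(curve$z[idx], curve$force[idx])
  dslope <- contact$slope - zeroline$slope
  if (abs(dslope) <= 1e-12 * max(abs(contact$slope), abs(zeroline$slope), 1)) {
    cp_not_found(curve, "contact and zero lines are parallel")
  }
  z_star <- (zeroline$intercept - contact$intercept) / dslope
  if (z_star < min(curve$z) || z_star > max(curve$z)) {
    cp_not_found(curve, "line intersection falls outside the curve")
  }
  new_contact_point(curve, which.min(abs(curve$z - z_star)), "fit_intersection")
}

#' Locate the contact point by a selectable routine
#'
#' Dispatches to [cp_derivative_smooth()], [cp_lowest_value_smooth()] or
#' [cp_fit_intersection()].  The contact point's z coordinate is the pixel's
#' zero-force height, used to build the topography map.
#'
#' @inheritParams cp_fit_intersection
#' @param method One of `"derivative_smooth"`, `"lowest_value_smooth"`,
#'   `"fit_intersection"`.
#' @returns An `fv_contact_point`.
#' @export
find_contact <- function(curve, method = c(
                           "derivative_smooth", "lowest_value_smooth",
                           "fit_intersection"
                         ),
                         params = fv_cp_params(), zeroline = NULL) {
  method <- rlang::arg_match(method)
  switch(method,
    derivative_smooth = cp_derivative_smooth(curve, params),
    lowest_value_smooth = cp_lowest_value_smooth(curve, params),
    fit_intersection = cp_fit_intersection(curve, params, zeroline)
  )
}
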