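# In-code fixtures shared across the test files.

# a bare fv_curve in physical units, optionally already baseline-free
make_curve <- function(z, force, baseline_removed = TRUE, grid_x = 0L, grid_y = 0L) {
  fcvolume:::new_fv_curve(
    tibble::tibble(z = z, deflection = force, force = force),
    deflection_unit = "N", calibrated = TRUE,
    baseline_removed = baseline_removed, direction = "approach",
    grid_x = grid_x, grid_y = grid_y
  )
}

# piecewise-linear "kink" curve: zero until z = z0, slope m after
make_kink_curve <- function(z0 = 60, m = 1, z = seq(0, 100, by = 0.5)) {
  make_curve(z, pmax(z - z0, 0) * m)
}

# an ideal indentation curve F = B * delta^2 (+ intercept)
make_hertz_ind <- function(B = 0.001, delta = seq(0, 100, length.out = 201),
                           intercept = 0, grid_x = 0L, grid_y = 0L) {
  out <- tibble::tibble(delta = delta, force = B * delta^2 + intercept)
  class(out) <- c("fv_indentation", class(out))
  attr(out, "grid_x") <- grid_x
  attr(out, "grid_y") <- grid_y
  out
}

# slope of F vs delta^2 predicted by the tip model for E in kPa
tip_b_for_e <- function(e_kpa, tip) {
  2 * tip$c0 / (pi * (1 - tip$nu^2) * tan(tip$alpha_deg * pi / 180)) * e_kpa * 1e-6
}

# small, fast synthetic scene (coarser curves than the validation default)
quick_scene <- function(..., samples_per_curve = 600L) {
  synthetic_scene(..., samples_per_curve = samples_per_curve)
}

# analysis tuned to the synthetic-scene geometry (contact = upper half)
scene_analysis <- function(n_smooth = 3L, cp_method = "derivative_smooth", ...) {
  fv_analysis(
    zeroline_window = c(0, 40), cp_method = cp_method, n_smooth = n_smooth, ...
  )
}

# write one fv_curve in the raw two-column dialect
write_curve_txt <- function(curve, path) {
  writeLines(sprintf("%.17g %.17g", curve$z, curve$deflection), path)
  path
}

# literal brute-force scan oracle for the derivative CP routine: walks the
# *same* smoothed-derivative array sample by sample from the scan start
scan_oracle_derivative <- function(curve, n_smooth) {
  fs <- moving_average(curve$force, n_smooth)
  d <- moving_average(fcvolume:::finite_derivative(fs, curve$z), n_smooth)
  N <- length(d)
  tol <- 1e-12 * max(abs(d))
  start <- N - fcvolume:::smooth_halfwidth(n_smooth)
  for (i in start:1) {
    if (abs(d[i]) <= tol) return(i)
    if (i < N && sign(d[i]) != 0 && sign(d[i + 1]) != 0 &&
      sign(d[i]) != sign(d[i + 1])) {
      return(i)
    }
  }
  NA_integer_
}
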