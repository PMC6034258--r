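#' Rigid-substrate reference line
#'
#' On an incompressible substrate every nanometre of stage advance past
#' contact bends the cantilever by one nanometre, so the force grows as
#' \eqn{F_{rigid}(z) = K_C (z - z_{cp})} (equivalently the deflection signal
#' grows with slope `S` V/nm).  The indentation depth of a real curve is its
#' shortfall relative to this line.
#'
#' @param curve A calibrated, baseline-subtracted approach `fv_curve`.
#' @param cp An `fv_contact_point`.
#' @param params An [fv_acquisition()].
#' @returns A tibble with columns `z` (nm) and `force_rigid` (nN) over the
#'   contact region.
#' @export
rigid_reference <- function(curve, cp, params) {
  idx <- cp$index:nrow(curve)
  tibble::tibble(
    z = curve$z[idx],
    force_rigid = params$cantilever_k * (curve$z[idx] - cp$z_cp)
  )
}

#' Indentation curve of one pixel
#'
#' Over the contact region (contact point to maximum load) the cantilever's
#' own bending \eqn{d = F / K_C} (identically \eqn{D / S} for volt input) is
#' subtracted from the stage travel to give the penetration into the sample,
#' \eqn{\delta = (z - z_{cp}) - d}.  Samples with negative \eqn{\delta}
#' (noise around contact) are dropped, not clamped, so they cannot bias the
#' \eqn{F} vs \eqn{\delta^2} fit near the origin; the number dropped is kept
#' in the `n_dropped` attribute.
#'
#' @inheritParams rigid_reference
#' @returns An `fv_indentation` tibble with columns `delta` (nm) and `force`
#'   (nN); \eqn{\delta^2} is formed at fit time.
#' @export
compute_indentation <- function(curve, cp, params) {
  stopifnot(isTRUE(attr(curve, "baseline_removed")))
  idx <- cp$index:nrow(curve)
  if (length(idx) < 2L) {
    abort("fewer than 2 contact samples", class = "fcv_indent_error")
  }
  travel <- curve$z[idx] - cp$z_cp
  d <- curve$force[idx] / params$cantilever_k
  delta <- travel - d
  keep <- delta >= 0
  n_dropped <- sum(!keep)
  delta <- delta[keep]
  force <- curve$force[idx][keep]
  if (length(delta) < 2L) {
    abort(sprintf(
      "fewer than 2 valid indentation samples at grid position (%s, %s)",
      attr(curve, "grid_x"), attr(curve, "grid_y")
    ), class = "fcv_indent_error")
  }
  out <- tibble::tibble(delta = delta, force = force)
  class(out) <- c("fv_indentation", class(out))
  attr(out, "grid_x") <- attr(curve, "grid_x")
  attr(out, "grid_y") <- attr(curve, "grid_y")
  attr(out, "z_cp") <- cp$z_cp
  attr(out, "cp_method") <- cp$method
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Save an indentation curve as `ind_<x>_<y>.txt`
#'
#' Two whitespace-delimited columns, \eqn{\delta} in nm and force in nN, with
#' `.` decimals; the file name carries the 0-based grid position so the map
#' can be refitted later without redoing the contact analysis.
#'
#' @param ind An `fv_indentation` (with grid position attributes).
#' @param dir Output directory.
#' @returns The file path, invisibly.
#' @export
save_indentation <- function(ind, dir) {
  x <- attr(ind, "grid_x")
  y <- attr(ind, "grid_y")
  path <- file.path(dir, sprintf("ind_%d_%d.txt", x, y))
  writeLines(
    sprintf(
      "%s %s",
      formatC(ind$delta, format = "g", digits = 17),
      formatC(ind$force, format = "g", digits = 17)
    ),
    path
  )
  invisible(path)
}

#' Read an `ind_<x>_<y>.txt` indentation file
#'
#' @param path File written by [save_indentation()].
#' @returns An `fv_indentation` tibble; the grid position is recovered from
#'   the file name.
#' @export
read_indentation <- function(path) {
  m <- regmatches(
    basename(path),
    regexec("^ind_([0-9]+)_([0-9]+)\\.txt$", basename(path))
  )[[1]]
  if (length(m) != 3L) {
    abort(sprintf("'%s' is not an ind_<x>_<y>.txt file", path),
      class = "fcv_parse_error"
    )
  }
  vals <- scan(text = gsub(",", ".", readLines(path, warn = FALSE), fixed = TRUE),
    what = numeric(), quiet = TRUE
  )
  if (length(vals) < 4L || length(vals) %% 2L != 0L) {
    abort(sprintf("'%s': malformed 2-column indentation file", path),
      class = "fcv_format_error"
    )
  }
  m2 <- matrix(vals, ncol = 2L, byrow = TRUE)
  out <- tibble::tibble(delta = m2[, 1], force = m2[, 2])
  class(out) <- c("fv_indentation", class(out))
  attr(out, "grid_x") <- as.integer(m[2])
  attr(out, "grid_y") <- as.integer(m[3])
  out
}
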