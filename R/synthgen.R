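#' Define a synthetic force-volume scene
#'
#' A scene is a fully specified virtual sample plus instrument: a 2-D Young's
#' modulus field (kPa), a topography field (nm), an optional mask of rigid
#' (incompressible) pixels, the calibration constants of the virtual
#' cantilever and detector, and the load schedule.  [generate_curve()] and
#' [generate_map()] run the contact model forward to emit raw curve files in
#' exactly the text dialect the analysis reads, so every pipeline stage can
#' be validated against known ground truth.
#'
#' For every pixel the approach spans a non-contact run of
#' `noncontact_frac` times the contact travel, places the contact point
#' exactly on a sample, and ends at the stage position where the force
#' balance reaches `max_load`.  At each contact sample the cantilever
#' deflection `d` solves \eqn{K_C d = F_{tip}(z - z_{cp} - d)} (by bisection,
#' which also covers layered depth profiles), with
#' \eqn{F_{tip}(\delta) = C_0 2 E \delta^2 / (\pi (1-\nu^2) \tan\alpha)}.
#' Raw files store Z in stage units (nm divided by `z_stage_sensitivity`)
#' and deflection in volts (`d` times `S`) with a linear baseline and
#' optional seeded Gaussian noise; per-pixel noise streams depend only on
#' the scene seed and the pixel position, so acquisition order never changes
#' a pixel's data.
#'
#' @param e_field Matrix of Young's moduli in kPa, indexed `[y + 1, x + 1]`,
#'   or a scalar recycled over the grid.
#' @param height_field Topography in nm (matrix or scalar).  Taller pixels
#'   make contact earlier, i.e. at smaller stage advance.
#' @param rigid_mask Logical matrix marking incompressible pixels.
#' @param n_x,n_y Grid size, required when the fields are scalars.
#' @param layer Optional depth profile: `list(thickness = t_nm, e_deep =
#'   E_kPa)` stiffens every pixel below `t_nm` of penetration (a soft layer
#'   over a stiff substrate, for tomography validation).
#' @param cantilever_k,detector_sensitivity,z_stage_sensitivity Virtual
#'   instrument calibration (N/m, V/nm, nm per raw Z unit).
#' @param tip The [fv_tip()] used in the forward model.
#' @param max_load Per-curve maximum load, nN.
#' @param samples_per_curve Samples in the approach half.
#' @param noncontact_frac Non-contact run length as a fraction of the
#'   contact travel.
#' @param noise_sd Gaussian force noise, as a fraction of `max_load`.
#' @param baseline_offset_v,baseline_tilt_v_per_nm Linear baseline added to
#'   the deflection signal (volts; exercised by the zeroline subtraction).
#' @param include_withdraw Append a mirrored withdraw half (elastic,
#'   hysteresis-free) so files are "complete" curves.
#' @param seed Scene seed; together with the pixel position it determines
#'   every random draw.
#' @returns An `fv_scene` list.
#' @export
synthetic_scene <- function(e_field = 10, height_field = 0, rigid_mask = NULL,
                            n_x = NULL, n_y = NULL, layer = NULL,
                            cantilever_k = 0.164,
                            detector_sensitivity = 0.025,
                            z_stage_sensitivity = 1,
                            tip = fv_tip("pyramid4", 23.5),
                            max_load = 2,
                            samples_per_curve = 2000L,
                            noncontact_frac = 1,
                            noise_sd = 0,
                            baseline_offset_v = 0.05,
                            baseline_tilt_v_per_nm = 1e-5,
                            include_withdraw = TRUE,
                            seed = 1L) {
  if (is.matrix(e_field)) {
    n_y <- nrow(e_field)
    n_x <- ncol(e_field)
  } else {
    if (is.null(n_x) || is.null(n_y)) {
      abort("n_x and n_y are required with scalar fields", class = "fcv_param_error")
    }
    e_field <- matrix(e_field, n_y, n_x)
  }
  if (!is.matrix(height_field)) height_field <- matrix(height_field, n_y, n_x)
  if (is.null(rigid_mask)) rigid_mask <- matrix(FALSE, n_y, n_x)
  stopifnot(
    all(dim(height_field) == c(n_y, n_x)),
    all(dim(rigid_mask) == c(n_y, n_x)),
    all(e_field > 0), max_load > 0, samples_per_curve >= 16L
  )
  structure(list(
    e_field = e_field, height_field = height_field, rigid_mask = rigid_mask,
    n_x = as.integer(n_x), n_y = as.integer(n_y), layer = layer,
    cantilever_k = cantilever_k, detector_sensitivity = detector_sensitivity,
    z_stage_sensitivity = z_stage_sensitivity, tip = tip,
    max_load = max_load, samples_per_curve = as.integer(samples_per_curve),
    noncontact_frac = noncontact_frac, noise_sd = noise_sd,
    baseline_offset_v = baseline_offset_v,
    baseline_tilt_v_per_nm = baseline_tilt_v_per_nm,
    include_withdraw = include_withdraw, seed = as.integer(seed)
  ), class = "fv_scene")
}

#' Two-region validation scene
#'
#' Left half soft, right half stiff, with a topography step along the same
#' boundary — the standard end-to-end closure fixture.
#'
#' @param n_x,n_y Grid size.
#' @param e_soft,e_stiff Region moduli, kPa.
#' @param step_nm Height of the left region above the right, nm.
#' @param ... Passed to [synthetic_scene()].
#' @returns An `fv_scene`.
#' @export
scene_two_region <- function(n_x = 20, n_y = 20, e_soft = 10, e_stiff = 50,
                             step_nm = 200, ...) {
  left <- matrix(rep(seq_len(n_x) <= n_x %/% 2, each = n_y), n_y, n_x)
  synthetic_scene(
    e_field = ifelse(left, e_soft, e_stiff),
    height_field = ifelse(left, step_nm, 0),
    ...
  )
}

# tip-model force at penetration delta (vectorised), kPa fields -> nN/nm^2
scene_force_fun <- function(scene, e_kpa) {
  k1 <- tip_prefactor(scene$tip) * e_kpa * 1e-6
  if (is.null(scene$layer)) {
    function(delta) k1 * delta^2
  } else {
    t_nm <- scene$layer$thickness
    k2 <- tip_prefactor(scene$tip) * scene$layer$e_deep * 1e-6
    function(delta) {
      ifelse(delta <= t_nm,
        k1 * delta^2,
        k1 * t_nm^2 + k2 * (delta^2 - t_nm^2)
      )
    }
  }
}

# penetration at which the force law reaches the target load
scene_delta_max <- function(scene, e_kpa) {
  k1 <- tip_prefactor(scene$tip) * e_kpa * 1e-6
  f_break <- if (is.null(scene$layer)) Inf else k1 * scene$layer$thickness^2
  if (scene$max_load <= f_break) {
    sqrt(scene$max_load / k1)
  } else {
    k2 <- tip_prefactor(scene$tip) * scene$layer$e_deep * 1e-6
    sqrt(scene$layer$thickness^2 + (scene$max_load - f_break) / k2)
  }
}

#' Generate one raw synthetic force curve
#'
#' Runs the forward contact model for a single pixel and returns the raw
#' two-column content (Z in stage units, deflection in volts) exactly as
#' [generate_map()] writes it.
#'
#' @param scene An [fv_scene][synthetic_scene()].
#' @param x,y 0-based pixel position (selects modulus, height, rigidity and
#'   the pixel's noise stream).
#' @returns An `fv_curve` tibble with columns `z`, `deflection`.
#' @export
generate_curve <- function(scene, x = 0L, y = 0L) {
  e_kpa <- scene$e_field[y + 1L, x + 1L]
  height <- scene$height_field[y + 1L, x + 1L]
  rigid <- scene$rigid_mask[y + 1L, x + 1L]
  kc <- scene$cantilever_k
  n <- scene$samples_per_curve
  z_ref <- max(scene$height_field)
  z_cp <- z_ref - height # taller pixels meet the tip sooner

  d_max <- scene$max_load / kc
  delta_max <- if (rigid) 0 else scene_delta_max(scene, e_kpa)
  travel <- delta_max + d_max
  n_nc <- max(4L, round((n - 1L) * scene$noncontact_frac / (1 + scene$noncontact_frac)))
  dz <- travel / (n - 1L - n_nc)
  z <- z_cp + dz * (seq_len(n) - 1L - n_nc) # z_cp exactly at sample n_nc + 1

  adv <- pmax(z - z_cp, 0)
  if (rigid) {
    d_nm <- adv
  } else {
    f_tip <- scene_force_fun(scene, e_kpa)
    lo <- numeric(n)
    hi <- adv
    for (it in seq_len(64L)) {
      mid <- (lo + hi) / 2
      up <- kc * mid < f_tip(adv - mid)
      lo[up] <- mid[up]
      hi[!up] <- mid[!up]
    }
    d_nm <- (lo + hi) / 2
    d_nm[adv == 0] <- 0
  }

  s <- scene$detector_sensitivity
  volts <- d_nm * s +
    scene$baseline_offset_v + scene$baseline_tilt_v_per_nm * z
  if (scene$include_withdraw) {
    z <- c(z, rev(z)[-1])
    volts <- c(volts, rev(volts)[-1])
  }
  if (scene$noise_sd > 0) {
    pixel_seed <- (scene$seed * 10007L + y * scene$n_x + x) %% 2147483647L
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(pixel_seed)
    volts <- volts + rnorm(length(volts),
      sd = scene$noise_sd * scene$max_load * s / kc
    )
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else set.seed(NULL)
  }
  new_fv_curve(
    tibble::tibble(z = z / scene$z_stage_sensitivity, deflection = volts),
    deflection_unit = "V", direction = if (scene$include_withdraw) "full" else "approach",
    grid_x = as.integer(x), grid_y = as.integer(y)
  )
}

#' Write a complete synthetic force-volume data set
#'
#' One text file per pixel, named and ordered per the chosen convention,
#' plus (optionally) the ground-truth modulus and height matrices in the
#' same labelled-matrix dialect the analysis exports.
#'
#' @param scene An [fv_scene][synthetic_scene()].
#' @param dir Output directory (created if missing).
#' @param naming_mode `"explicit"` (`<prefix>_<x>_<y>_ref.txt`) or
#'   `"progressive"` (`<prefix>_<i>.txt` in acquisition order).
#' @param scan_modality `"row_x_row"` or `"raster"` (serpentine) acquisition
#'   order, which determines progressive indices.
#' @param prefix Map-name prefix.
#' @param write_truth Also write `truth_E.txt` (kPa) and `truth_height.txt`
#'   (nm, as contact-point z) to a `truth/` subdirectory.
#' @returns Invisibly, a tibble of the files written with their grid
#'   positions.
#' @export
generate_map <- function(scene, dir, naming_mode = c("explicit", "progressive"),
                         scan_modality = c("row_x_row", "raster"),
                         prefix = "syn", write_truth = TRUE) {
  naming_mode <- match.arg(naming_mode)
  scan_modality <- match.arg(scan_modality)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  order_tbl <- decode_position(
    seq_len(scene$n_x * scene$n_y), scene$n_x, scan_modality
  )
  files <- character(nrow(order_tbl))
  for (i in seq_len(nrow(order_tbl))) {
    x <- order_tbl$grid_x[i]
    y <- order_tbl$grid_y[i]
    fname <- if (naming_mode == "explicit") {
      sprintf("%s_%d_%d_ref.txt", prefix, x, y)
    } else {
      sprintf("%s_%d.txt", prefix, i)
    }
    curve <- generate_curve(scene, x, y)
    writeLines(
      sprintf(
        "%s %s",
        formatC(curve$z, format = "g", digits = 17),
        formatC(curve$deflection, format = "g", digits = 17)
      ),
      file.path(dir, fname)
    )
    files[i] <- fname
  }
  if (write_truth) {
    tdir <- file.path(dir, "truth")
    dir.create(tdir, showWarnings = FALSE)
    grid <- tidyr::expand_grid(y = 0:(scene$n_y - 1), x = 0:(scene$n_x - 1))
    write_map_txt(
      fv_map(grid$x, grid$y, scene$e_field[cbind(grid$y + 1, grid$x + 1)],
        unit = "kPa", name = "truth_E"
      ),
      file.path(tdir, "truth_E.txt")
    )
    z_ref <- max(scene$height_field)
    write_map_txt(
      fv_map(grid$x, grid$y,
        z_ref - scene$height_field[cbind(grid$y + 1, grid$x + 1)],
        unit = "nm", name = "truth_height"
      ),
      file.path(tdir, "truth_height.txt")
    )
  }
  invisible(tibble::tibble(
    file = files, grid_x = order_tbl$grid_x, grid_y = order_tbl$grid_y
  ))
}

#' Acquisition parameters matching a synthetic scene
#'
#' @param scene An [fv_scene][synthetic_scene()].
#' @param naming_mode,scan_modality Layout the files were written with.
#' @returns An [fv_acquisition()] that calibrates the scene's files back to
#'   physical units.
#' @export
scene_acquisition <- function(scene, naming_mode = "explicit",
                              scan_modality = "row_x_row") {
  fv_acquisition(
    z_stage_sensitivity = scene$z_stage_sensitivity,
    cantilever_k = scene$cantilever_k,
    detector_sensitivity = scene$detector_sensitivity,
    deflection_unit = "V",
    curves_per_row = scene$n_x,
    scan_modality = scan_modality,
    naming_mode = naming_mode,
    curve_type = if (scene$include_withdraw) "complete" else "approach_only"
  )
}
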