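#' Analysis parameters
#'
#' The per-curve analysis knobs shared by all batch routines.
#'
#' @param zeroline_window Percentage pair of the curve used for the zeroline
#'   fit (0% = farthest from the surface, 100% = maximum load).
#' @param cp_method Contact-point routine, see [find_contact()].
#' @param n_smooth Moving-average window for the smoothing-based routines.
#' @param contact_window Whole-curve percentage pair for the
#'   `fit_intersection` contact-line fit.
#' @param stiffness_window Contact-line percentage pair for [fit_stiffness()]
#'   (0% = contact point, 100% = maximum load).
#' @param fit_window Depth-percentage pair for [fit_modulus()].
#' @param tip An [fv_tip()].
#' @param e_unit Output unit for modulus maps (`"kPa"`, `"MPa"`, `"GPa"`).
#' @param preview_every Emit a diagnostic record for one curve every this
#'   many curves when diagnostics are enabled.
#' @param optimizer_mode `"random"` or `"insert_position"`.
#' @param optimizer_positions For `"insert_position"`: a list (or 2-column
#'   matrix) of `c(x, y)` pixels for the optimizer preview.
#' @returns An `fv_analysis` list.
#' @export
fv_analysis <- function(zeroline_window = c(0, 70),
                        cp_method = c(
                          "derivative_smooth", "lowest_value_smooth",
                          "fit_intersection"
                        ),
                        n_smooth = 5L,
                        contact_window = c(90, 100),
                        stiffness_window = c(0, 100),
                        fit_window = c(0, 100),
                        tip = fv_tip(),
                        e_unit = c("kPa", "MPa", "GPa"),
                        preview_every = 100L,
                        optimizer_mode = c("random", "insert_position"),
                        optimizer_positions = NULL) {
  structure(list(
    zeroline_window = zeroline_window,
    cp_method = rlang::arg_match(cp_method),
    cp_params = fv_cp_params(n_smooth, contact_window, zeroline_window),
    stiffness_window = stiffness_window,
    fit_window = fit_window,
    tip = tip,
    e_unit = match.arg(e_unit),
    preview_every = as.integer(preview_every),
    optimizer_mode = match.arg(optimizer_mode),
    optimizer_positions = optimizer_positions
  ), class = "fv_analysis")
}

#' Full run configuration
#'
#' @param acquisition An [fv_acquisition()].
#' @param analysis An [fv_analysis()].
#' @param region An [fv_region()].
#' @returns An `fv_config` list; serializable with [write_config()].
#' @export
fv_config <- function(acquisition, analysis = fv_analysis(),
                      region = fv_region()) {
  stopifnot(
    inherits(acquisition, "fv_acquisition"),
    inherits(analysis, "fv_analysis"),
    inherits(region, "fv_region")
  )
  structure(list(acquisition = acquisition, analysis = analysis, region = region),
    class = "fv_config"
  )
}

#' Write / read a run configuration as YAML
#'
#' A run is fully reproducible from the configuration file plus the data
#' directory; the batch routines snapshot the resolved configuration into
#' their output directory.
#'
#' @param config An [fv_config()].
#' @param path YAML file path.
#' @returns `write_config()` returns `path` invisibly; `read_config()`
#'   returns the reconstructed `fv_config`.
#' @export
write_config <- function(config, path) {
  acq <- unclass(config$acquisition)
  ana <- unclass(config$analysis)
  yaml::write_yaml(list(
    acquisition = acq[!vapply(acq, is.null, TRUE)],
    analysis = list(
      zeroline_window = ana$zeroline_window,
      cp_method = ana$cp_method,
      n_smooth = ana$cp_params$n_smooth,
      contact_window = ana$cp_params$contact_window,
      stiffness_window = ana$stiffness_window,
      fit_window = ana$fit_window,
      tip = unclass(ana$tip),
      e_unit = ana$e_unit,
      preview_every = ana$preview_every,
      optimizer_mode = ana$optimizer_mode,
      optimizer_positions = ana$optimizer_positions
    ),
    region = unclass(config$region)
  ), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  acq <- do.call(fv_acquisition, raw$acquisition)
  a <- raw$analysis
  ana <- fv_analysis(
    zeroline_window = unlist(a$zeroline_window),
    cp_method = a$cp_method,
    n_smooth = a$n_smooth,
    contact_window = unlist(a$contact_window),
    stiffness_window = unlist(a$stiffness_window),
    fit_window = unlist(a$fit_window),
    tip = fv_tip(a$tip$shape, a$tip$alpha_deg, a$tip$c0, a$tip$nu),
    e_unit = a$e_unit,
    preview_every = a$preview_every,
    optimizer_mode = a$optimizer_mode,
    optimizer_positions = a$optimizer_positions
  )
  region <- if (raw$region$mode == "whole_map") {
    fv_region()
  } else {
    fv_region(
      c(raw$region$start_x, raw$region$start_y),
      c(raw$region$end_x, raw$region$end_y)
    )
  }
  fv_config(acq, ana, region)
}

# load -> split -> calibrate -> zeroline -> subtract -> contact point
process_curve <- function(path, config, grid_x = NA_integer_, grid_y = NA_integer_) {
  acq <- config$acquisition
  ana <- config$analysis
  curve <- load_curve(path, acq$deflection_unit)
  attr(curve, "grid_x") <- grid_x
  attr(curve, "grid_y") <- grid_y
  curve <- split_approach(curve, acq$curve_type)
  curve <- to_physical(curve, acq)
  zl <- fit_zeroline(curve, ana$zeroline_window)
  curve <- subtract_zeroline(curve, zl)
  cp <- find_contact(curve, ana$cp_method, ana$cp_params)
  list(curve = curve, zeroline = zl, cp = cp)
}

region_files <- function(config, data_dir, prefix = NULL) {
  files <- list_curve_files(
    data_dir,
    naming_mode = config$acquisition$naming_mode,
    curves_per_row = config$acquisition$curves_per_row,
    scan_modality = config$acquisition$scan_modality,
    prefix = prefix
  )
  select_region(files, config$region)
}

finish_maps <- function(maps, out_dir, failures, n) {
  if (failures > 0L) {
    inform(sprintf("%d of %d curves failed and were mapped to NaN", failures, n))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (m in maps) {
      nm <- attr(m, "map_name")
      write_map_txt(m, file.path(out_dir, paste0(nm, ".txt")))
      if (any(is.finite(m$value))) {
        write_map_image(m, file.path(out_dir, paste0(nm, ".png")))
      }
    }
  }
  maps
}

#' Multicontact: topography and contact-stiffness maps
#'
#' For every curve in the selected region: calibrate, subtract the zeroline,
#' locate the contact point, and fit the contact-line slope.  The contact
#' point's z gives the zero-force topography; the slope gives a
#' model-free stiffness.  Suited to hard, barely deformable samples.
#'
#' @param config An [fv_config()].
#' @param data_dir Directory of per-curve `.txt` files.
#' @param out_dir Optional output directory: maps are exported as labelled
#'   text matrices and PNG images, and the resolved configuration is
#'   snapshotted.
#' @param prefix Optional map-name prefix filter.
#' @returns A named list of [fv_map()]s: `topography` (nm) and `stiffness`
#'   (nN/nm).  Failed pixels are `NaN`.
#' @export
run_multicontact <- function(config, data_dir, out_dir = NULL, prefix = NULL) {
  files <- region_files(config, data_dir, prefix)
  ana <- config$analysis
  res <- purrr::pmap(
    list(files$path, files$grid_x, files$grid_y),
    function(path, gx, gy) {
      tryCatch({
        st <- process_curve(path, config, gx, gy)
        sf <- fit_stiffness(st$curve, st$cp, ana$stiffness_window, config$acquisition)
        c(st$cp$z_cp, sf$slope)
      }, error = function(e) c(NaN, NaN))
    }
  )
  res <- do.call(rbind, res)
  maps <- list(
    topography = fv_map(files$grid_x, files$grid_y, res[, 1],
      unit = "nm", name = "topography"
    ),
    stiffness = fv_map(files$grid_x, files$grid_y, res[, 2],
      unit = "nN/nm", name = "stiffness"
    )
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_config(config, file.path(out_dir, "config.yaml"))
  }
  finish_maps(maps, out_dir, sum(!is.finite(res[, 2])), nrow(files))
}

#' Multicurve: indentation curves plus preliminary modulus map
#'
#' For every curve in the region: calibrate, subtract the zeroline, locate
#' the contact point, build the indentation curve, save it as
#' `ind_<x>_<y>.txt`, and fit a preliminary Young's modulus over the full
#' 0--100% depth window with the configured tip model.  The preliminary map
#' is always reported in kPa; refit depth windows later with
#' [run_multindentation()].  Recommended for soft, deformable samples.
#'
#' @inheritParams run_multicontact
#' @param ind_dir Directory receiving the `ind_*.txt` files (defaults to
#'   `out_dir`, or a temporary directory when both are `NULL`).
#' @returns A named list: `topography` (nm), `preliminary_e` (kPa),
#'   `ind_dir`, `ind_files` (paths written).
#' @export
run_multicurve <- function(config, data_dir, out_dir = NULL, ind_dir = NULL,
                           prefix = NULL) {
  files <- region_files(config, data_dir, prefix)
  ana <- config$analysis
  ind_dir <- ind_dir %||% out_dir %||% tempfile("ind")
  dir.create(ind_dir, showWarnings = FALSE, recursive = TRUE)
  res <- purrr::pmap(
    list(files$path, files$grid_x, files$grid_y),
    function(path, gx, gy) {
      tryCatch({
        st <- process_curve(path, config, gx, gy)
        ind <- compute_indentation(st$curve, st$cp, config$acquisition)
        f <- save_indentation(ind, ind_dir)
        mod <- fit_modulus(ind, ana$tip, c(0, 100), unit = "kPa")
        list(z = st$cp$z_cp, e = mod$E, file = f)
      }, error = function(e) list(z = NaN, e = NaN, file = NA_character_))
    }
  )
  maps <- list(
    topography = fv_map(files$grid_x, files$grid_y,
      purrr::map_dbl(res, "z"), unit = "nm", name = "topography"
    ),
    preliminary_e = fv_map(files$grid_x, files$grid_y,
      purrr::map_dbl(res, "e"), unit = "kPa", name = "preliminary_E"
    )
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_config(config, file.path(out_dir, "config.yaml"))
  }
  maps <- finish_maps(maps, out_dir, sum(!is.finite(maps$preliminary_e$value)),
    nrow(files)
  )
  c(maps, list(
    ind_dir = ind_dir,
    ind_files = purrr::map_chr(res, "file")
  ))
}

#' Multindentation: quantitative modulus map from saved indentation curves
#'
#' Refits the `ind_<x>_<y>.txt` files written by [run_multicurve()] with the
#' configured tip model over an arbitrary depth window, without re-deriving
#' the indentation curves.  Re-running with different windows is the force
#' tomography mode: each run's output file names carry the window
#' extremities (`modulus_40_75.txt`, ...).
#'
#' @param config An [fv_config()] (tip model, unit and region are used; the
#'   region is re-applied independently of the Multicurve run).
#' @param ind_dir Directory of `ind_*.txt` files.
#' @param window Depth-percentage pair to fit.
#' @param out_dir Optional export directory.
#' @param unit Override of the configured modulus unit.
#' @returns An [fv_map()] of Young's modulus; missing or failed pixels are
#'   `NaN`.
#' @export
run_multindentation <- function(config, ind_dir, window = NULL,
                                out_dir = NULL, unit = NULL) {
  ana <- config$analysis
  window <- window %||% ana$fit_window
  unit <- unit %||% ana$e_unit
  paths <- list.files(ind_dir, pattern = "^ind_[0-9]+_[0-9]+\\.txt$",
    full.names = TRUE
  )
  if (length(paths) == 0L) {
    abort(sprintf("no ind_*.txt files in '%s'", ind_dir), class = "fcv_io_error")
  }
  pos <- dplyr::bind_rows(purrr::map(paths, function(p) {
    m <- regmatches(basename(p), regexec("^ind_([0-9]+)_([0-9]+)\\.txt$", basename(p)))[[1]]
    tibble::tibble(path = p, grid_x = as.integer(m[2]), grid_y = as.integer(m[3]))
  }))
  pos <- select_region(pos, config$region)
  vals <- purrr::map_dbl(pos$path, function(p) {
    tryCatch(fit_modulus(read_indentation(p), ana$tip, window, unit)$E,
      error = function(e) NaN
    )
  })
  nm <- sprintf("modulus_%g_%g", window[1], window[2])
  map <- fv_map(pos$grid_x, pos$grid_y, vals, unit = unit, name = nm)
  finish_maps(list(map), out_dir, sum(!is.finite(vals)), nrow(pos))[[1]]
}

#' Optimizer: staged preview of four curves
#'
#' Before committing to a full-map run, inspect every analysis stage on four
#' curves — selected at random (seeded) or at user-given positions — to tune
#' the zeroline window, the contact-point routine and its smoothing, and the
#' fit window.  For each selected curve the bundle holds the processed
#' curve, the zeroline fit, the contact point, the indentation curve and the
#' F vs \eqn{\delta^2} modulus fit; per-curve failures are reported in place
#' of the stages, without aborting the others.
#'
#' @inheritParams run_multicontact
#' @param n_curves Number of curves to preview.
#' @param seed Seed for the random selection mode.
#' @returns A list with `selection` (tibble of pixels) and `curves` (one
#'   diagnostics bundle per selection).
#' @export
run_optimizer <- function(config, data_dir, n_curves = 4L, seed = 1L,
                          out_dir = NULL, prefix = NULL) {
  files <- region_files(config, data_dir, prefix)
  ana <- config$analysis
  if (ana$optimizer_mode == "insert_position") {
    pos <- ana$optimizer_positions
    if (is.list(pos)) pos <- do.call(rbind, pos)
    sel <- dplyr::inner_join(
      files,
      tibble::tibble(grid_x = as.integer(pos[, 1]), grid_y = as.integer(pos[, 2])),
      by = c("grid_x", "grid_y")
    )
  } else {
    if (nrow(files) < n_curves) {
      warn("fewer curves than requested; previewing all of them")
      sel <- files
    } else {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      set.seed(seed)
      sel <- files[sort(sample.int(nrow(files), n_curves)), ]
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
    }
  }
  bundles <- purrr::pmap(
    list(sel$path, sel$grid_x, sel$grid_y),
    function(path, gx, gy) {
      tryCatch({
        st <- process_curve(path, config, gx, gy)
        ind <- compute_indentation(st$curve, st$cp, config$acquisition)
        mod <- fit_modulus(ind, ana$tip, ana$fit_window, unit = ana$e_unit)
        rigid <- rigid_reference(st$curve, st$cp, config$acquisition)
        list(
          grid_x = gx, grid_y = gy, curve = st$curve, zeroline = st$zeroline,
          cp = st$cp, rigid = rigid, indentation = ind, modulus = mod,
          error = NULL
        )
      }, error = function(e) {
        list(grid_x = gx, grid_y = gy, error = conditionMessage(e))
      })
    }
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_config(config, file.path(out_dir, "config.yaml"))
    for (b in bundles) {
      if (is.null(b$error)) {
        ggplot2::ggsave(
          file.path(out_dir, sprintf("optimizer_%d_%d.png", b$grid_x, b$grid_y)),
          plot_cp_diagnostic(b$curve, b$cp),
          width = 6, height = 4, dpi = 96
        )
      }
    }
  }
  list(selection = dplyr::select(sel, "grid_x", "grid_y", "file"), curves = bundles)
}
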