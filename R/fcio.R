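#' Parse a force-curve file name into its grid position
#'
#' Force-volume acquisitions name the per-pixel text files in one of two
#' dialects: *explicit*, `mapname<posx>_<posy>_<reference image>` (e.g.
#' `map01_32_15_img4` is the curve at column 32, row 15, with reference image
#' `img4`), or *progressive*, `mapname<N>` (e.g. `map01_33` is the 33rd curve
#' acquired).  For progressive names the grid position additionally depends on
#' the scan modality; resolve it with [decode_position()].
#'
#' @param name File name (with or without a `.txt` extension).
#' @param naming_mode `"explicit"` or `"progressive"`.
#' @returns A one-row tibble with columns `file`, `map_prefix`, `grid_x`,
#'   `grid_y`, `progressive_index` (columns not applicable to the mode are
#'   `NA`).  Grid coordinates are 0-based; progressive indices are 1-based.
#' @examples
#' parse_filename("map01_32_15_img4", "explicit")
#' parse_filename("map01_33", "progressive")
#' @export
parse_filename <- function(name, naming_mode = c("explicit", "progressive")) {
  naming_mode <- match.arg(naming_mode)
  base <- sub("\\.txt$", "", basename(name), ignore.case = TRUE)
  tokens <- strsplit(base, "_", fixed = TRUE)[[1]]
  is_int <- function(s) grepl("^[0-9]+$", s)
  fail <- function(why) {
    abort(sprintf("cannot parse '%s' as a %s-mode file name: %s",
      name, naming_mode, why
    ), class = "fcv_parse_error")
  }
  if (naming_mode == "explicit") {
    n <- length(tokens)
    if (n < 3L) fail("expected <prefix>_<x>_<y>_<reference>")
    x_tok <- tokens[n - 2L]
    y_tok <- tokens[n - 1L]
    if (!is_int(x_tok) || !is_int(y_tok)) {
      fail("position fields are not non-negative integers")
    }
    prefix <- if (n > 3L) paste0(paste(tokens[1:(n - 3L)], collapse = "_"), "_") else ""
    tibble::tibble(
      file = name, map_prefix = prefix,
      grid_x = as.integer(x_tok), grid_y = as.integer(y_tok),
      progressive_index = NA_integer_
    )
  } else {
    n <- length(tokens)
    idx_tok <- tokens[n]
    if (!is_int(idx_tok)) fail("trailing field is not an integer index")
    idx <- as.integer(idx_tok)
    if (idx < 1L) fail("progressive indices are 1-based")
    prefix <- if (n > 1L) paste0(paste(tokens[1:(n - 1L)], collapse = "_"), "_") else ""
    tibble::tibble(
      file = name, map_prefix = prefix,
      grid_x = NA_integer_, grid_y = NA_integer_,
      progressive_index = idx
    )
  }
}

#' Resolve a progressive curve index to grid coordinates
#'
#' In `row_x_row` scanning every line is acquired left to right; in `raster`
#' (serpentine) scanning odd lines (1st, 3rd, ...) run left to right and even
#' lines right to left, so the column order of even rows is mirrored.
#'
#' @param progressive_index 1-based acquisition index (vectorised).
#' @param curves_per_row Number of curves per map row.
#' @param scan_modality `"row_x_row"` or `"raster"`.
#' @param n_rows Optional declared number of rows; indices beyond
#'   `n_rows * curves_per_row` raise an error.
#' @returns A tibble with 0-based columns `grid_x`, `grid_y`.
#' @examples
#' decode_position(33, curves_per_row = 16)              # x 0, y 2
#' decode_position(20, curves_per_row = 16, "raster")    # mirrored row: x 12
#' @export
decode_position <- function(progressive_index, curves_per_row,
                            scan_modality = c("row_x_row", "raster"),
                            n_rows = NULL) {
  scan_modality <- match.arg(scan_modality)
  i <- as.integer(progressive_index)
  if (any(i < 1L)) {
    abort("progressive indices are 1-based", class = "fcv_range_error")
  }
  if (!is.null(n_rows) && any(i > n_rows * curves_per_row)) {
    abort("progressive index exceeds the declared map size",
      class = "fcv_range_error"
    )
  }
  grid_y <- (i - 1L) %/% curves_per_row
  grid_x <- (i - 1L) %% curves_per_row
  if (scan_modality == "raster") {
    even_row <- grid_y %% 2L == 1L # 1-based rows 2, 4, ... are mirrored
    grid_x[even_row] <- curves_per_row - 1L - grid_x[even_row]
  }
  tibble::tibble(grid_x = grid_x, grid_y = grid_y)
}

#' List and position the curve files of a force-volume directory
#'
#' @param dir Directory containing one `.txt` file per force curve.
#' @param naming_mode,curves_per_row,scan_modality See [parse_filename()] and
#'   [decode_position()].
#' @param prefix Optional map-name prefix used to filter files.
#' @returns A tibble with one row per curve file: `path`, `file`,
#'   `map_prefix`, `grid_x`, `grid_y`, `progressive_index`.
#' @export
list_curve_files <- function(dir, naming_mode = c("explicit", "progressive"),
                             curves_per_row = NULL,
                             scan_modality = c("row_x_row", "raster"),
                             prefix = NULL) {
  naming_mode <- match.arg(naming_mode)
  scan_modality <- match.arg(scan_modality)
  paths <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
  if (!is.null(prefix)) {
    paths <- paths[startsWith(basename(paths), prefix)]
  }
  if (length(paths) == 0L) {
    abort(sprintf("no curve .txt files found in '%s'", dir),
      class = "fcv_io_error"
    )
  }
  rec <- purrr::map(
    basename(paths),
    function(f) tryCatch(parse_filename(f, naming_mode), error = function(e) NULL)
  )
  bad <- vapply(rec, is.null, TRUE)
  if (any(bad)) {
    warn(sprintf(
      "skipping %d file(s) not matching the %s naming pattern (e.g. '%s')",
      sum(bad), naming_mode, basename(paths)[which(bad)[1]]
    ))
    paths <- paths[!bad]
    rec <- rec[!bad]
  }
  if (length(paths) == 0L) {
    abort(sprintf("no parseable curve files in '%s'", dir), class = "fcv_io_error")
  }
  rec <- dplyr::bind_rows(rec)
  rec$path <- paths
  if (naming_mode == "progressive") {
    if (is.null(curves_per_row)) {
      abort("curves_per_row is required for progressive naming",
        class = "fcv_config_error"
      )
    }
    pos <- decode_position(rec$progressive_index, curves_per_row, scan_modality)
    rec$grid_x <- pos$grid_x
    rec$grid_y <- pos$grid_y
  }
  dplyr::arrange(
    dplyr::select(
      rec, "path", "file", "map_prefix", "grid_x", "grid_y",
      "progressive_index"
    ),
    .data$grid_y, .data$grid_x
  )
}

new_fv_curve <- function(df, deflection_unit = "V", calibrated = FALSE,
                         baseline_removed = FALSE, direction = "full",
                         grid_x = NA_integer_, grid_y = NA_integer_) {
  out <- tibble::as_tibble(df)
  class(out) <- c("fv_curve", class(out))
  attr(out, "deflection_unit") <- deflection_unit
  attr(out, "calibrated") <- calibrated
  attr(out, "baseline_removed") <- baseline_removed
  attr(out, "direction") <- direction
  attr(out, "grid_x") <- grid_x
  attr(out, "grid_y") <- grid_y
  out
}

# carry fv_curve attributes over a transformed data frame
keep_curve_attrs <- function(df, template, ...) {
  upd <- list(...)
  a <- function(k) if (k %in% names(upd)) upd[[k]] else attr(template, k)
  new_fv_curve(df,
    deflection_unit = a("deflection_unit"), calibrated = a("calibrated"),
    baseline_removed = a("baseline_removed"), direction = a("direction"),
    grid_x = a("grid_x"), grid_y = a("grid_y")
  )
}

#' Read one force curve from a two-column text file
#'
#' Each file holds a single curve as whitespace- or tab-delimited
#' Z-displacement and deflection columns.  Decimal commas are accepted on
#' input.  No calibration is applied: Z stays in the instrument's stage units
#' and deflection in the declared unit.
#'
#' @param path File path.
#' @param deflection_unit `"V"` (photodiode volts) or `"N"` (already a force;
#'   the file's second column is then taken as nN downstream with
#'   `K_C = S = 1`).
#' @param skip Number of leading header lines to skip (default 0, strict).
#' @returns An `fv_curve` tibble with columns `z`, `deflection`.
#' @export
load_curve <- function(path, deflection_unit = c("V", "N"), skip = 0L) {
  deflection_unit <- match.arg(deflection_unit)
  lines <- readLines(path, warn = FALSE)
  if (skip > 0L) lines <- lines[-seq_len(min(skip, length(lines)))]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 4L) {
    abort(sprintf("'%s': fewer than 4 samples", path), class = "fcv_format_error")
  }
  lines <- gsub(",", ".", lines, fixed = TRUE)
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    abort(sprintf(
      "'%s': line %d has fewer than 2 columns", path, which(nf < 2L)[1] + skip
    ), class = "fcv_format_error")
  }
  z <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 1L)))
  d <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  bad <- which(is.na(z) | is.na(d))
  if (length(bad) > 0L) {
    abort(sprintf("'%s': non-numeric data on line %d", path, bad[1] + skip),
      class = "fcv_format_error"
    )
  }
  new_fv_curve(tibble::tibble(z = z, deflection = d),
    deflection_unit = deflection_unit
  )
}

#' Define a rectangular analysis region
#'
#' @param start,end 0-based `c(x, y)` grid coordinates of the bottom-left and
#'   upper-right corners (both inclusive); omit both for the whole map.
#' @returns An `fv_region` object.
#' @examples
#' fv_region()                      # whole map
#' fv_region(c(10, 10), c(19, 19))  # 10 x 10 sub-map
#' @export
fv_region <- function(start = NULL, end = NULL) {
  if (is.null(start) && is.null(end)) {
    out <- list(mode = "whole_map")
  } else {
    stopifnot(length(start) == 2L, length(end) == 2L)
    if (start[1] > end[1] || start[2] > end[2]) {
      abort("region corners are inverted: start must be the bottom-left corner",
        class = "fcv_region_error"
      )
    }
    if (any(c(start, end) < 0)) {
      abort("region corners must be non-negative", class = "fcv_region_error")
    }
    out <- list(
      mode = "partial",
      start_x = as.integer(start[1]), start_y = as.integer(start[2]),
      end_x = as.integer(end[1]), end_y = as.integer(end[2])
    )
  }
  structure(out, class = "fv_region")
}

#' Restrict a curve-file table (or map) to a rectangular region
#'
#' @param records A tibble with `grid_x`/`grid_y` columns (from
#'   [list_curve_files()]) or an `fv_map`.
#' @param region An [fv_region()].
#' @returns The rows falling inside the inclusive rectangle.
#' @export
select_region <- function(records, region = fv_region()) {
  stopifnot(inherits(region, "fv_region"))
  xcol <- if ("grid_x" %in% names(records)) "grid_x" else "x"
  ycol <- if ("grid_y" %in% names(records)) "grid_y" else "y"
  if (region$mode == "whole_map") {
    return(records)
  }
  if (region$end_x > max(records[[xcol]]) || region$end_y > max(records[[ycol]])) {
    abort("region corner outside the map bounds", class = "fcv_region_error")
  }
  dplyr::filter(
    records,
    .data[[xcol]] >= region$start_x, .data[[xcol]] <= region$end_x,
    .data[[ycol]] >= region$start_y, .data[[ycol]] <= region$end_y
  )
}

#' Construct a result map
#'
#' A result map is a tidy grid of one scalar per pixel (topography height,
#' contact-line slope, or Young's modulus), with missing pixels as `NaN`.
#'
#' @param x,y 0-based grid coordinates (vectors of equal length).
#' @param value Per-pixel values.
#' @param unit Unit string carried in the attribute (`"nm"`, `"nN/nm"`,
#'   `"kPa"`, ...).
#' @param name Map name, used in export file names.
#' @returns An `fv_map` tibble with columns `x`, `y`, `value`.
#' @export
fv_map <- function(x, y, value, unit = "", name = "map") {
  stopifnot(length(x) == length(y), length(y) == length(value))
  out <- dplyr::arrange(
    tibble::tibble(x = as.integer(x), y = as.integer(y), value = as.numeric(value)),
    .data$y, .data$x
  )
  class(out) <- c("fv_map", class(out))
  attr(out, "unit") <- unit
  attr(out, "map_name") <- name
  out
}

#' Convert a result map to a labelled matrix
#'
#' @param map An [fv_map()].
#' @returns A numeric matrix with `dimnames` giving the Y (rows) and X
#'   (columns) grid positions; row 1 is the lowest `y`.
#' @export
map_matrix <- function(map) {
  xs <- sort(unique(map$x))
  ys <- sort(unique(map$y))
  m <- matrix(NaN, nrow = length(ys), ncol = length(xs),
    dimnames = list(as.character(ys), as.character(xs))
  )
  m[cbind(match(map$y, ys), match(map$x, xs))] <- map$value
  m
}

#' Write a result map as a labelled text matrix
#'
#' The exported dialect matches the Gwyddion raw-text import recipe: the
#' first row holds the X positions (after a corner sentinel of `0`), the
#' first column of every later row holds the Y position, values are
#' whitespace-delimited with `.` decimals and missing pixels written as
#' `nan`.  Importing with "start from line" 1 and "each row skip" 1 strips
#' exactly the labels.
#'
#' @param map An [fv_map()].
#' @param path Output file path.
#' @returns `path`, invisibly.
#' @export
write_map_txt <- function(map, path) {
  m <- map_matrix(map)
  fmt <- function(v) {
    s <- formatC(v, format = "g", digits = 17)
    s[!is.finite(v) & is.nan(v)] <- "nan"
    s
  }
  header <- paste(c("0", colnames(m)), collapse = " ")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], fmt(m[i, ])), collapse = " ")
  }, "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}

#' Read a labelled text matrix back into a result map
#'
#' @param path File written by [write_map_txt()].
#' @param unit,name Attributes for the reconstructed map.
#' @returns An [fv_map()].
#' @export
read_map_txt <- function(path, unit = "", name = "map") {
  lines <- readLines(path, warn = FALSE)
  lines <- gsub(",", ".", lines[nzchar(trimws(lines))], fixed = TRUE)
  fields <- strsplit(trimws(lines), "[ \t]+")
  xs <- as.numeric(fields[[1]][-1])
  rows <- fields[-1]
  ys <- as.numeric(vapply(rows, `[[`, "", 1L))
  vals <- lapply(rows, function(f) as.numeric(f[-1]))
  grid <- tidyr::expand_grid(y = ys, x = xs) # row-major like the file
  fv_map(grid$x, grid$y, unlist(vals), unit = unit, name = name)
}

#' Write a result map as a PNG image
#'
#' Values are mapped linearly from their finite minimum (black) to maximum
#' (white); one pixel per grid cell, row `y = 0` at the bottom of the image.
#' Missing pixels are rendered mid-grey.
#'
#' @param map An [fv_map()].
#' @param path Output `.png` path.
#' @returns `path`, invisibly.
#' @export
write_map_image <- function(map, path) {
  m <- map_matrix(map)
  if (!any(is.finite(m))) {
    abort("cannot render an all-missing map", class = "fcv_io_error")
  }
  rng <- range(m[is.finite(m)])
  g <- if (diff(rng) == 0) {
    matrix(0.5, nrow(m), ncol(m))
  } else {
    (m - rng[1]) / diff(rng)
  }
  g[!is.finite(g)] <- 0.5
  png::writePNG(g[rev(seq_len(nrow(g))), , drop = FALSE], target = path)
  invisible(path)
}
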